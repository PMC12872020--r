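species,genus,family,functional_group,wood_type,allometric_key,candidate,excluded,exclusion_reason
Picea glauca,Picea,Pinaceae,1A,softwood,Picea glauca,TRUE,FALSE,
Picea pungens,Picea,Pinaceae,1A,softwood,softwood,TRUE,FALSE,
Abies balsamea,Abies,Pinaceae,1A,softwood,softwood,TRUE,FALSE,
Thuja occidentalis,Thuja,Cupressaceae,1A,softwood,softwood,TRUE,FALSE,
Pinus strobus,Pinus,Pinaceae,1A,softwood,softwood,TRUE,FALSE,
Pinus resinosa,Pinus,Pinaceae,1B,softwood,softwood,TRUE,FALSE,
Pinus nigra,Pinus,Pinaceae,1B,softwood,softwood,TRUE,FALSE,
Larix laricina,Larix,Pinaceae,1B,softwood,softwood,TRUE,FALSE,
Juniperus virginiana,Juniperus,Cupressaceae,1B,softwood,softwood,TRUE,FALSE,
Ginkgo biloba,Ginkgo,Ginkgoaceae,1B,softwood,softwood,TRUE,FALSE,
Acer saccharum,Acer,Sapindaceae,2A,hardwood,Acer saccharum,TRUE,FALSE,
Acer platanoides,Acer,Sapindaceae,2A,hardwood,hardwood,TRUE,FALSE,
Tilia cordata,Tilia,Malvaceae,2A,hardwood,hardwood,TRUE,FALSE,
Tilia americana,Tilia,Malvaceae,2A,hardwood,hardwood,TRUE,FALSE,
Magnolia acuminata,Magnolia,Magnoliaceae,2A,hardwood,hardwood,TRUE,FALSE,
Fagus grandifolia,Fagus,Fagaceae,2A,hardwood,hardwood,TRUE,FALSE,
Aesculus hippocastanum,Aesculus,Sapindaceae,2B,hardwood,hardwood,TRUE,FALSE,
Aesculus glabra,Aesculus,Sapindaceae,2B,hardwood,hardwood,TRUE,FALSE,
Aesculus flava,Aesculus,Sapindaceae,2B,hardwood,hardwood,TRUE,FALSE,
Ulmus americana,Ulmus,Ulmaceae,2C,hardwood,hardwood,TRUE,FALSE,
Celtis occidentalis,Celtis,Cannabaceae,2C,hardwood,hardwood,TRUE,FALSE,
Acer rubrum,Acer,Sapindaceae,2C,hardwood,hardwood,TRUE,FALSE,
Acer saccharinum,Acer,Sapindaceae,2C,hardwood,hardwood,TRUE,FALSE,
Acer negundo,Acer,Sapindaceae,2C,hardwood,hardwood,TRUE,FALSE,
Fraxinus pennsylvanica,Fraxinus,Oleaceae,2C,hardwood,hardwood,FALSE,TRUE,pest
Fraxinus americana,Fraxinus,Oleaceae,2C,hardwood,hardwood,FALSE,TRUE,pest
Sorbus aucuparia,Sorbus,Rosaceae,3A,hardwood,hardwood,TRUE,FALSE,
Pyrus calleryana,Pyrus,Rosaceae,3A,hardwood,hardwood,TRUE,FALSE,
Crataegus crus-galli,Crataegus,Rosaceae,3A,hardwood,hardwood,TRUE,FALSE,
Amelanchier canadensis,Amelanchier,Rosaceae,3A,hardwood,hardwood,TRUE,FALSE,
Syringa reticulata,Syringa,Oleaceae,3A,hardwood,hardwood,TRUE,FALSE,
Prunus virginiana,Prunus,Rosaceae,3B,hardwood,hardwood,TRUE,FALSE,
Malus baccata,Malus,Rosaceae,3B,hardwood,hardwood,TRUE,FALSE,
Catalpa speciosa,Catalpa,Bignoniaceae,3B,hardwood,hardwood,TRUE,FALSE,
Maackia amurensis,Maackia,Fabaceae,3B,hardwood,hardwood,TRUE,FALSE,
Quercus rubra,Quercus,Fagaceae,4A,hardwood,hardwood,TRUE,FALSE,
Quercus macrocarpa,Quercus,Fagaceae,4A,hardwood,hardwood,TRUE,FALSE,
Juglans nigra,Juglans,Juglandaceae,4A,hardwood,hardwood,TRUE,FALSE,
Juglans cinerea,Juglans,Juglandaceae,4A,hardwood,hardwood,FALSE,TRUE,pest
Carya ovata,Carya,Juglandaceae,4A,hardwood,hardwood,TRUE,FALSE,
Gleditsia triacanthos,Gleditsia,Fabaceae,4B,hardwood,hardwood,TRUE,FALSE,
Robinia pseudoacacia,Robinia,Fabaceae,4B,hardwood,hardwood,TRUE,FALSE,
Gymnocladus dioicus,Gymnocladus,Fabaceae,4B,hardwood,hardwood,TRUE,FALSE,
Populus deltoides,Populus,Salicaceae,5,hardwood,hardwood,TRUE,FALSE,
Populus tremuloides,Populus,Salicaceae,5,hardwood,hardwood,TRUE,FALSE,
Salix alba,Salix,Salicaceae,5,hardwood,hardwood,TRUE,FALSE,
Betula papyrifera,Betula,Betulaceae,5,hardwood,hardwood,TRUE,FALSE,
Alnus glutinosa,Alnus,Betulaceae,5,hardwood,hardwood,TRUE,FALSE,
Rhamnus cathartica,Rhamnus,Rhamnaceae,,hardwood,hardwood,FALSE,TRUE,invasive
Rhamnus frangula,Rhamnus,Rhamnaceae,,hardwood,hardwood,FALSE,TRUE,invasive
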