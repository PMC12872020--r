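park,n_trees,n_to_plant
Beaubien,257,13
Maisonneuve,6329,316
Jarry,2299,115
Gabriel-Lalemant,176,9
Delorme,1025,51
Ahuntsic,944,47
La Fontaine,2862,143
Lacoursiere,346,17
Angrignon,935,47
Jeanne-Mance,407,20
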