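park,sp_richness_before,sp_diversity_before,sp_richness_after,sp_diversity_after,sp_richness_improvement_pct,sp_diversity_improvement_pct,fg_richness_before,fg_diversity_before,fg_richness_after,fg_diversity_after,fg_diversity_improvement_pct
Beaubien,40,24.9,50,28.2,25.0,13.3,10,8.7,10,9.0,3.4
Maisonneuve,81,29.1,89,33.2,9.9,14.1,10,7.8,10,8.2,5.1
Jarry,76,32.0,82,35.5,7.9,10.9,10,8.3,10,8.7,4.8
Gabriel-Lalemant,47,27.0,56,31.3,19.1,15.9,10,7.0,10,7.4,5.7
Delorme,68,26.6,76,30.4,11.8,14.3,10,7.3,10,7.8,6.8
Ahuntsic,73,25.9,82,29.9,12.3,15.4,10,6.4,10,6.9,7.8
La Fontaine,89,22.6,98,26.1,10.1,15.5,10,5.5,10,6.0,9.1
Lacoursiere,32,13.5,40,15.8,25.0,17.0,10,5.0,10,5.6,12.0
Angrignon,41,15.8,51,18.9,24.4,19.6,10,4.8,10,5.5,14.6
Jeanne-Mance,25,4.3,34,5.3,36.0,23.3,8,2.5,10,2.9,16.0
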