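species,composition,sex,n_populations,n_units,n_datapoints,mean_unit_size,sd_unit_size,dispersal,breeding,litter
Cryptomys damarensis,related,F,3,15,15,6.2,2.8,philopatric,singular,polytocous
Ctenodactylus gundi,related,F,1,2,2,3.0,1.4,philopatric,plural,polytocous
Ctenodactylus gundi,related,M,1,2,2,2.5,0.7,philopatric,NA,NA
Marmota flaviventris,related,F,2,2,2,2.5,0.7,philopatric,plural,polytocous
Cynomys ludovicianus,related,F,1,3,3,2,NA,philopatric,plural,polytocous
Macaca mulatta,mix-related,F,1,5,9,53.1,23.8,philopatric,plural,monotocous
Macaca fascicularis,mix-related,F,1,1,1,13,NA,philopatric,plural,monotocous
Papio cynocephalus,mix-related,F,1,3,3,9.7,1.2,philopatric,plural,monotocous
Cercopithecus mitis,mix-related,F,1,3,3,15.2,5.2,philopatric,plural,monotocous
Pan troglodytes,mix-related,F,1,1,1,39,NA,disperse,plural,monotocous
Pan troglodytes,mix-related,M,1,1,1,12,NA,philopatric,NA,NA
Cebus capucinus,related,F,1,2,2,3.0,1.4,philopatric,plural,monotocous
Myotis bechsteinii,mix-related,F,1,4,4,22.0,9.0,philopatric,plural,monotocous
Eptesicus fuscus,mix-related,F,1,1,1,37.5,NA,philopatric,plural,monotocous
Artibeus jamaicensis,related,M,1,2,2,2.0,0.0,unclear,plural,monotocous
Orcinus orca,related,F,1,12,12,3.2,1.2,philopatric,plural,monotocous
Orcinus orca,related,M,1,5,5,2.4,0.5,philopatric,NA,NA
Canis lupus,related,F,2,3,4,2.0,0.0,philopatric,singular,polytocous
Canis lupus,related,M,1,1,1,3,NA,unclear,NA,NA
Cuon alpinus,related,F,1,1,1,2,NA,disperse,singular,polytocous
Vulpes vulpes,related,F,1,1,1,5,NA,philopatric,plural,polytocous
Crocuta crocuta,mix-related,F,1,1,1,21,NA,philopatric,plural,monotocous
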