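taxon,order,habitat,is_salmonid,species
Clupea_pallasii,Clupeiformes,pelagic,FALSE,Pacific herring
Engraulis_mordax,Clupeiformes,pelagic,FALSE,Northern anchovy
Alosa_sapidissima,Clupeiformes,pelagic,FALSE,American shad
Gadus_chalcogrammus,Gadiformes,demersal,FALSE,Walleye pollock
Gadus_macrocephalus,Gadiformes,demersal,FALSE,Pacific cod
Merluccius_productus,Gadiformes,demersal,FALSE,Pacific hake
Microgadus_proximus,Gadiformes,demersal,FALSE,Pacific tomcod
Oncorhynchus_tshawytscha,Salmoniformes,pelagic,TRUE,Chinook salmon
Oncorhynchus_kisutch,Salmoniformes,pelagic,TRUE,Coho salmon
Oncorhynchus_nerka,Salmoniformes,pelagic,TRUE,Sockeye salmon
Oncorhynchus_keta,Salmoniformes,pelagic,TRUE,Chum salmon
Oncorhynchus_gorbuscha,Salmoniformes,pelagic,TRUE,Pink salmon
Oncorhynchus_mykiss,Salmoniformes,pelagic,TRUE,Steelhead
Parophrys_vetulus,Pleuronectiformes,benthic,FALSE,English sole
Platichthys_stellatus,Pleuronectiformes,benthic,FALSE,Starry flounder
Citharichthys_sordidus,Pleuronectiformes,benthic,FALSE,Pacific sanddab
Sebastes_spp,Scorpaeniformes,benthic,FALSE,Rockfish
Leptocottus_armatus,Scorpaeniformes,benthic,FALSE,Pacific staghorn sculpin
Ammodytes_hexapterus,Perciformes,pelagic,FALSE,Pacific sand lance
Embiotoca_lateralis,Perciformes,benthic,FALSE,Striped surfperch
Cymatogaster_aggregata,Perciformes,benthic,FALSE,Shiner perch
Porichthys_notatus,Batrachoidiformes,benthic,FALSE,Plainfin midshipman
Raja_rhina,Rajiformes,benthic,FALSE,Longnose skate
Hydrolagus_colliei,Chimaeriformes,demersal,FALSE,Spotted ratfish
Entosphenus_tridentatus,Petromyzontiformes,pelagic,FALSE,Pacific lamprey
Thaleichthys_pacificus,Osmeriformes,pelagic,FALSE,Eulachon
Hypomesus_pretiosus,Osmeriformes,pelagic,FALSE,Surf smelt
Gasterosteus_aculeatus,Gasterosteiformes,pelagic,FALSE,Threespine stickleback
Doryteuthis_opalescens,Cephalopoda,pelagic,FALSE,Market squid
Enteroctopus_dofleini,Cephalopoda,benthic,FALSE,Giant Pacific octopus
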