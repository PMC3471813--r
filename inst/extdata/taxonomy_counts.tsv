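phylum	n_species
Acidobacteria	1
Actinobacteria	5
Aquificae	1
Bacteroidetes	3
Chlamydiae	1
Chlorobi	1
Chloroflexi	4
Crenarchaeota	3
Cyanobacteria	9
Deinococcus-Thermus	2
Euryarchaeota	10
Fibrobacteres	1
Firmicutes	15
Fusobacteria	1
Nanoarchaeota	1
Planctomycetes	1
Proteobacteria	49
Spirochaetes	2
Tenericutes	3
Thermotogae	1
Virus	3
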