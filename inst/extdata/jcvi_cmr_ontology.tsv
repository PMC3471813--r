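category	subcategory
Amino acid biosynthesis	Aromatic amino acid family
Amino acid biosynthesis	Aspartate family
Amino acid biosynthesis	Glutamate family
Amino acid biosynthesis	Histidine family
Amino acid biosynthesis	Pyruvate family
Amino acid biosynthesis	Serine family
Biosynthesis of cofactors, prosthetic groups, and carriers	Biotin
Biosynthesis of cofactors, prosthetic groups, and carriers	Folic acid
Biosynthesis of cofactors, prosthetic groups, and carriers	Heme, porphyrin, and cobalamin
Biosynthesis of cofactors, prosthetic groups, and carriers	Menaquinone and ubiquinone
Biosynthesis of cofactors, prosthetic groups, and carriers	Pantothenate and coenzyme A
Biosynthesis of cofactors, prosthetic groups, and carriers	Pyridoxine
Biosynthesis of cofactors, prosthetic groups, and carriers	Riboflavin, FMN, and FAD
Biosynthesis of cofactors, prosthetic groups, and carriers	Thiamine
Cell envelope	Biosynthesis and degradation of surface polysaccharides and lipopolysaccharides
Cell envelope	Biosynthesis of murein sacculus and peptidoglycan
Cell envelope	Other
Cell envelope	Surface structures
Cellular processes	Adaptations to atypical conditions
Cellular processes	Cell division
Cellular processes	Chemotaxis and motility
Cellular processes	Detoxification
Cellular processes	DNA transformation
Cellular processes	Pathogenesis
Cellular processes	Sporulation and germination
Cellular processes	Toxin production and resistance
Central intermediary metabolism	Amino sugars
Central intermediary metabolism	Nitrogen metabolism
Central intermediary metabolism	One-carbon metabolism
Central intermediary metabolism	Other
Central intermediary metabolism	Phosphorus compounds
Central intermediary metabolism	Polyamine biosynthesis
Central intermediary metabolism	Sulfur metabolism
DNA metabolism	Chromosome-associated proteins
DNA metabolism	Degradation of DNA
DNA metabolism	DNA replication, recombination, and repair
DNA metabolism	Restriction/modification
Energy metabolism	Aerobic
Energy metabolism	Amino acids and amines
Energy metabolism	Anaerobic
Energy metabolism	ATP-proton motive force interconversion
Energy metabolism	Biosynthesis and degradation of polysaccharides
Energy metabolism	Electron transport
Energy metabolism	Entner-Doudoroff
Energy metabolism	Fermentation
Energy metabolism	Glycolysis/gluconeogenesis
Energy metabolism	Methanogenesis
Energy metabolism	Pentose phosphate pathway
Energy metabolism	Photosynthesis
Energy metabolism	Sugars
Energy metabolism	TCA cycle
Fatty acid and phospholipid metabolism	Biosynthesis
Fatty acid and phospholipid metabolism	Degradation
Mobile and extrachromosomal element functions	Phage functions
Mobile and extrachromosomal element functions	Plasmid functions
Mobile and extrachromosomal element functions	Prophage functions
Mobile and extrachromosomal element functions	Transposon functions
Protein fate	Degradation of proteins, peptides, and glycopeptides
Protein fate	Protein and peptide secretion and trafficking
Protein fate	Protein folding and stabilization
Protein fate	Protein modification and repair
Protein synthesis	Ribosomal proteins: synthesis and modification
Protein synthesis	Translation factors
Protein synthesis	tRNA aminoacylation
Protein synthesis	tRNA and rRNA base modification
Purines, pyrimidines, nucleosides, and nucleotides	2'-Deoxyribonucleotide metabolism
Purines, pyrimidines, nucleosides, and nucleotides	Nucleotide and nucleoside interconversions
Purines, pyrimidines, nucleosides, and nucleotides	Purine ribonucleotide biosynthesis
Purines, pyrimidines, nucleosides, and nucleotides	Pyrimidine ribonucleotide biosynthesis
Purines, pyrimidines, nucleosides, and nucleotides	Salvage of nucleosides and nucleotides
Purines, pyrimidines, nucleosides, and nucleotides	Sugar-nucleotide biosynthesis and conversions
Regulatory functions	DNA interactions
Regulatory functions	Protein interactions
Regulatory functions	RNA interactions
Regulatory functions	Small molecule interactions
Signal transduction	PTS
Signal transduction	Two-component systems
Signal transduction	Other
Transcription	Degradation of RNA
Transcription	DNA-dependent RNA polymerase
Transcription	RNA processing
Transcription	Transcription factors
Transport and binding proteins	Amino acids, peptides and amines
Transport and binding proteins	Anions
Transport and binding proteins	Carbohydrates, organic alcohols, and acids
Transport and binding proteins	Cations and iron carrying compounds
Transport and binding proteins	Nucleosides, purines and pyrimidines
Transport and binding proteins	Porins
Transport and binding proteins	Unknown substrate
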