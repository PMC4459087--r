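clade	clade_taxa	min_age	shape	spread
crown_Podicipedidae	Podiceps_cristatus;Tachybaptus_ruficollis	8.7	lognormal	1
stem_Anhingidae	Anhinga_melanogaster;Phalacrocorax_auritus	23	lognormal	1
stem_Pelecanidae	Balaeniceps_rex;Pelecanus_occidentalis;Scopus_umbretta	28.3	lognormal	1
crown_Mirandornithes	Phoeniconaias_minor;Phoenicoparrus_andinus;Phoenicoparrus_jamesi;Phoenicopterus_chilensis;Phoenicopterus_roseus;Phoenicopterus_ruber;Podiceps_cristatus;Tachybaptus_ruficollis	32.6	lognormal	1
stem_Sulidae	Anhinga_melanogaster;Phalacrocorax_auritus;Sula_leucogaster	33	lognormal	1
stem_Fregatidae	Anhinga_melanogaster;Fregata_minor;Phalacrocorax_auritus;Sula_leucogaster	51.8	lognormal	1
stem_Spheniscidae	Procellaria_aequinoctialis;Spheniscus_demersus	60.5	lognormal	1
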