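taxon	oldest	youngest	known_oldest	known_youngest	region	analyzed	count_in	attach_anchor	attach_mode	lineage_oldest
Aivukus_cedrosensis	8.0	5.5			EastPacific	TRUE	both			
Archaeodobenus_akamatsui	10.0	9.5			WestPacific	TRUE	both			
Dusignathus_santacruzensis	8.0	5.3			EastPacific	TRUE	both			
Dusignathus_seftoni	3.6	2.5			EastPacific	TRUE	both			
Gomphotaria_pugnax	6.6	4.9			EastPacific	TRUE	both			
Imagotaria_downsi	10.0	7.6	9.0	8.6	EastPacific	TRUE	both			
Kamtschatarctos_sinelnikovae	14.1	11.6			WestPacific	TRUE	both			
Neotherium_mirum	15.9	15.2			EastPacific	TRUE	both			
Odobenus_mandanoensis	0.8	0.5			WestPacific	FALSE	max_only	Odobenus_rosmarus	sister_to_tip	
Odobenus_rosmarus	0.1	0.0			Arctic	TRUE	both			
Ontocetus_emmonsi	5.3	1.1	4.9	1.8	Atlantic	TRUE	both			
Pelagiarctos	16.5	14.5			EastPacific	TRUE	both			
Pliopedia_pacifica	5.8	4.7			EastPacific	FALSE	max_only	Protodobenus_japonicus+Ontocetus_emmonsi+Valenictus_chulavistensis+Odobenus_rosmarus	on_stem_of_clade	
Pontolis_magnus	8.6	7.6			EastPacific	TRUE	both			
Proneotherium_repenningi	17.3	16.6			EastPacific	TRUE	both			
Protodobenus_japonicus	5.3	4.5			WestPacific	TRUE	both			
Prototaria_planicephala	16.4	15.1			WestPacific	FALSE	max_only	Prototaria_primigena	sister_to_tip	
Prototaria_primigena	15.1	14.7			WestPacific	TRUE	both			
Pseudotaria_muramotoi	10.0	9.5			WestPacific	TRUE	both			
Titanotaria_orangensis	6.6	5.8			EastPacific	TRUE	both			
Valenictus_chulavistensis	4.5	2.5			EastPacific	TRUE	both			5.3
Valenictus_imperialensis	5.2	4.2			EastPacific	FALSE	max_only	Valenictus_chulavistensis	sister_to_tip	
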