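(Proneotherium_repenningi,(Prototaria_primigena,(Pseudotaria_muramotoi,(Neotherium_mirum,Kamtschatarctos_sinelnikovae,(Archaeodobenus_akamatsui,(Pelagiarctos,(Titanotaria_orangensis,(Imagotaria_downsi,(Pontolis_magnus,(Gomphotaria_pugnax,(Dusignathus_seftoni,Dusignathus_santacruzensis,(Aivukus_cedrosensis,(Protodobenus_japonicus,Ontocetus_emmonsi,(Valenictus_chulavistensis,Odobenus_rosmarus))))))))))))));
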