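category,taxon_class,F,N,V
Lumbricidae,Annelida,1,3,1493.33
Achatinidae,Mollusca,5,23,1869.09
Stylommatophora other,Mollusca,1,1,1.67
Araneae,Arachnida,20,146,990.90
Opiliones,Arachnida,13,96,841.44
Uropigi,Arachnida,1,19,1035.68
Scolopendridae,Scolopendromorpha,6,14,1074.99
Armadillidiidae,Isopoda,1,2,39.90
Blattidae,Insecta,5,45,815.22
Byrrhidae,Insecta,1,1,9.81
Elateroidea,Insecta,1,1,302.03
Culicidae,Insecta,1,1,14.65
Cicadellidae,Insecta,1,1,10.47
Pentatomidae,Insecta,2,2,159.15
Apidae,Insecta,1,2,198.87
Formicidae,Insecta,4,9,28.78
Termitidae,Insecta,3,10,63.52
Hepialidae,Insecta,1,1,133.97
Lepidoptera other,Insecta,1,1,70.52
Mantidae,Insecta,1,6,85.17
Acrididae,Insecta,4,19,247.76
Tetrigidae,Insecta,1,4,5.63
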