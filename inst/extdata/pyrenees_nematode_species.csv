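taxon,habitat,freq,abundance,adults,afp,ofp,mass_ug,moran_i,moran_sig,exclude
Achromadora terricola,T,2,4,4,1.000,1.000,0.782,NA,NA,FALSE
Anatonchus dolichurus,S,12,112,36,1.000,1.000,77.429,0.045,FALSE,FALSE
Aphanolaimus aquaticus,"S,L",2,3,3,1.000,1.000,0.816,NA,NA,FALSE
Aporcelaimellus obtusicaudatus,T,24,53,42,0.902,0.929,9.986,0.000,FALSE,FALSE
Clarkus papillatus,"T,S",2,2,2,1.000,1.000,1.390,NA,NA,FALSE
Coomansus zschokkei,T,9,14,8,0.583,0.625,13.062,0.033,FALSE,FALSE
Crocodorylaimus flavomaculatus,"S,L",9,36,32,0.669,0.594,1.582,-0.002,FALSE,FALSE
Dorylaimus stagnalis,L,42,1509,1088,0.626,0.659,21.875,0.012,FALSE,FALSE
Dorylaimus sp.,,8,130,111,0.651,0.604,42.497,-0.045,FALSE,FALSE
Epidorylaimus consobrinus,"T,S",44,382,332,0.999,0.997,1.541,0.028,FALSE,FALSE
Ethmolaimus cf. pratensis,L,4,7,6,0.167,0.333,1.157,0.144,TRUE,FALSE
Eudorylaimus similis,S,7,11,9,1.000,1.000,6.714,0.020,FALSE,FALSE
Eutobrilus grandipapillatus,"S,L",31,467,303,0.838,0.818,4.463,0.088,TRUE,FALSE
Ironus longicaudatus,"S,L",17,205,159,0.993,0.987,0.997,-0.016,FALSE,FALSE
Ironus tenuicaudatus,"T,S,L",16,269,219,0.566,0.548,10.463,0.138,TRUE,FALSE
Ischiodorylaimus cf. cognatus,L,1,4,4,0.000,0.000,39.555,NA,NA,FALSE
Mesodorylaimus cf. conurus,L,4,7,7,0.792,0.714,2.844,0.056,FALSE,FALSE
Monhystera cf. paludicola,L,2,5,4,0.667,0.500,0.815,NA,NA,FALSE
Mononchus truncatus,"S,L",19,110,91,1.000,1.000,4.944,0.028,FALSE,FALSE
Paractinolaimus macrolaimus,"S,L",16,170,138,0.766,0.536,10.819,0.111,TRUE,FALSE
Plectus aquatilis,L,8,35,23,1.000,1.000,1.303,-0.030,FALSE,FALSE
Plectus cirratus,L,4,5,1,1.000,1.000,2.449,NA,NA,FALSE
Prionchulus muscorum,"T,S,L",2,2,1,1.000,1.000,6.537,NA,NA,FALSE
Prionchulus cf. punctatus,"T,S,L",1,1,1,1.000,1.000,6.859,NA,NA,FALSE
Prodorylaimus filiarum,"T,S",1,12,9,0.222,0.222,2.363,NA,NA,FALSE
Prodorylaimus cf. rotundiceps,"T,S,L",5,17,9,1.000,1.000,3.426,-0.033,FALSE,FALSE
Semitobrilus pellucidus,L,15,46,35,0.929,0.943,2.649,0.055,FALSE,FALSE
Tobrilus gracilis,"S,L",8,45,36,0.804,0.833,6.315,0.064,FALSE,FALSE
Tobrilus sp.,,1,3,3,1.000,1.000,3.375,NA,NA,FALSE
Tripyla filicaudata,"T,S",1,15,11,0.909,0.909,1.528,NA,NA,FALSE
Tripyla glomerans,"T,S,L",35,302,234,0.669,0.624,17.787,-0.032,FALSE,FALSE
Mermithidae,,31,137,56,0.059,0.018,NA,NA,NA,TRUE
Indeterminate,,6,11,1,1.000,1.000,NA,NA,NA,TRUE
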