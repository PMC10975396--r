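family,unadapted_parent,origin,race,n_lines_tested
2,35-5,Sudan,Caudatum,2
12,PI 510763,Cameroon,Guinea,6
21,GRIF717,-,Caudatum-durra,11
22,PI 152828,Democratic Republic of the Congo,Caudatum,67
23,PI 248334,India,Durra-caudatum,11
24,PI 276839,Ethiopia,Durra,18
26,PI 454390,Ethiopia,Caudatum,14
27,PI 454426,Ethiopia,Durra-kafir,9
29,PI 454780,Ethiopia,Durra,6
30,PI 454791,Ethiopia,Durra,13
31,PI 482903,Zimbabwe,Durra,2
32,PI 494884,Zambia,Guinea-bicolor,10
33,PI 494891,Zambia,Guinea,5
34,PI 521191,Kenya,Durra-Caudatum,7
42,Pandora Wani,India,Durra,6
44,PM 11344,India,Caudatum,13
45,Manzano,Honduras,Durra,14
48,GRIF809,Sudan,Durra,73
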