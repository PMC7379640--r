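target,urban_class,group,model,C,q,n
t2,visitor,Chiroptera,LS,16.53,9,47
t3,visitor,Cetartiodactyla,WA + LS,11.46,13,68
t4,dweller,Eulipotyphla,Trait-only,32.01,8,24
t5,dweller,Rodentia,WA + LS,16.24,12,202
t6,dweller,Carnivora,DD + LS,15.64,12,92
t7,visitor,Chiroptera,BR + LS,14.68,10,47
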