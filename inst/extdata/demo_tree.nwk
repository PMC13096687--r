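((((Psychotria:35,Palicourea:35):40,Coffea:75):45,(Primula:60,Erica:60):60):20,((Linum:90,Quercus:90):25,Carex:115):25);
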