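(Monodelphis_domestica:147.7,(Loxodonta_africana:103.0,(((Canis_familiaris:53.0,Felis_catus:53.0):34.0,(Equus_caballus:83.0,(Sus_scrofa:63.0,Bos_taurus:63.0):20.0):4.0):10.4,((Mus_musculus:16.3,Rattus_norvegicus:16.3):71.7,(Callithrix_jacchus:43.0,(Macaca_mulatta:29.0,(Pongo_abelii:16.0,(Pan_troglodytes:6.7,Homo_sapiens:6.7):9.3):13.0):14.0):45.0):9.4):5.6):44.7);
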