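(Monodelphis_domestica:160.0,(Loxodonta_africana:105.0,(((Canis_familiaris:55.0,Felis_catus:55.0):30.0,(Equus_caballus:80.0,(Sus_scrofa:60.0,Bos_taurus:60.0):20.0):5.0):10.0,((Mus_musculus:20.0,Rattus_norvegicus:20.0):70.0,(Callithrix_jacchus:45.0,(Macaca_mulatta:31.0,(Pongo_abelii:18.0,(Pan_troglodytes:8.0,Homo_sapiens:8.0):10.0):13.0):14.0):45.0):5.0):10.0):55.0);
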