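species,cd33rsiglec_count,klk_count,tlr_count,fcgr_count,max_lifespan_years,body_weight_grams
Bos_taurus,7,16,10,4,20,750000
Callithrix_jacchus,7,15,10,4,22.8,290
Canis_familiaris,8,15,10,4,24,30000
Equus_caballus,8,15,10,4,57,400000
Felis_catus,6,15,9,4,30,4000
Homo_sapiens,10,15,10,8,122.5,62000
Loxodonta_africana,9,15,10,4,65.5,4500000
Macaca_mulatta,8,15,10,5,40,7000
Monodelphis_domestica,2,14,9,3,5.1,100
Mus_musculus,5,24,12,4,4,20.5
Pan_troglodytes,12,15,10,5,59.4,45000
Pongo_abelii,11,15,10,4,59,57000
Rattus_norvegicus,5,22,10,4,3.8,300
Sus_scrofa,7,15,10,4,27,135000
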