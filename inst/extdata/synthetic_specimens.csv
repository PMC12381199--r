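species,trait,value,n_specimens,specimen_id,source_year
Macaca_mulatta,mc1,31.2,4,,1998
Macaca_mulatta,mc1,33.0,2,,2004
Macaca_mulatta,mc2,44.8,4,,1998
Pan_troglodytes,mc1,42.1,1,AMNH-51202,1973
Pan_troglodytes,mc1,41.5,1,AMNH-51202,2011
Pan_troglodytes,mc1,44.0,1,MCZ-20041,2011
Pan_troglodytes,mc2,69.3,3,,2011
Homo_sapiens,mc1,46.7,25,,2015
Homo_sapiens,mc2,67.9,25,,2015
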