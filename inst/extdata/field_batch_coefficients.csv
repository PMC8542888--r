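compound,sorbent,k_field,k_batch
tetracycline,sand,1.4,NA
tetracycline,CH,12.2,1859
tetracycline,CHCHI,12.7,648
enrofloxacin,sand,<0.1,NA
enrofloxacin,CH,7.0,1315
enrofloxacin,CHCHI,8.4,1551
atrazine,sand,0.2,NA
atrazine,CH,24.6,292
atrazine,CHCHI,<0.1,279
diuron,sand,0.7,NA
diuron,CH,19.2,2405
diuron,CHCHI,1.7,866
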