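name,abbreviation,molecular_mass,pka,logp
acetaminophen,ACM,151,9.5,0.51
atrazine,ATR,215,1.68,2.61
diclofenac,DIC,296,4.15,4.51
enrofloxacin,ENFL,359,5.88-6.06;7.70-7.74,4.7
diuron,DRN,233,n/a,2.87
tetracycline,TC,444,multiple,0.09
oxytetracycline,OTC,460,multiple,-0.9
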