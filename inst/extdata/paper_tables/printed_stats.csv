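pair,scheme,agreement_pct,kappa,kappa_se
henninger_wood,yesno,100,1.0,0.0
henninger_garbowski,yesno,98.45,0.966,0.014
henninger_hankins,yesno,92.75,0.832,0.03
garbowski_wood,yesno,98.45,0.966,0.014
garbowski_hankins,yesno,91.19,0.799,0.032
hankins_wood,yesno,92.75,0.832,0.03
henninger_wood,easl,99.48,0.989,0.007
henninger_garbowski,easl,93.26,0.866,0.024
henninger_hankins,easl,92.23,0.832,0.029
garbowski_wood,easl,93.78,0.877,0.023
garbowski_hankins,easl,86.53,0.717,0.034
hankins_wood,easl,92.75,0.843,0.029
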