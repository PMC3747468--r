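name,bp,id,prr,p,pha,tw,mts_fe,trf_fe
Synthes,0,2.76,0.22,2,0,0.1,1220,40.25
A-Spine,0,4,0.1,2,0,0.1,628,40.77
Moss Miami,40,4.61,3,2.95,31.35,0.2,1268,33.53
Viper,cylindrical,4.4,3,2.87,29.93,0.33,1766,34.04
Optimal design,0,3.8,0.4,3.3,5,0.1,422,39.1
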