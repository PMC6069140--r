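api_name,wsv_ug_L,hbg_ug_L,protection_printed,ltd_mg_kg_d,total_uf,rsc,inconsistent_as_printed
Acetaminophen (one tablet/day),9,200,22,3.75,3000,0.2,TRUE
Acetaminophen (six tablets/day),50,200,4,22.5,3000,0.2,TRUE
Carbamazepine,0.9,40,44,1,3000,0.8,FALSE
17a-Ethinylestradiol,0.0001,0.0002,2,0.00044,3000,0.8,TRUE
Sulfamethoxazole,0.4,100,250,4.57,30000,0.8,FALSE
Venlafaxine,0.3,10,33,25,3000,0.8,TRUE
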