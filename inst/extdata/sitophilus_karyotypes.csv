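"species","diploid_number","auto_metacentric","auto_submetacentric","auto_subtelocentric","auto_telocentric","auto_dotlike","x_class","y_class","sex_system","b_min","b_max","sexpair_code","cband_code","dapi_code","cma3_code","nor_code","extra_categories"
"Sitophilus_zeamais",22,20,0,0,0,0,"metacentric","dot-like","Xyp",0,4,0,0,0,0,0,""
"Sitophilus_oryzae",22,18,2,0,0,0,"metacentric","metacentric","Xyp",0,0,1,0,0,1,1,""
"Sitophilus_granarius",24,16,6,0,0,0,"submetacentric","metacentric","Xyp",0,0,2,1,1,2,2,""
"Sitophilus_linearis",24,18,4,0,0,0,"submetacentric","subtelocentric","neo-XY",0,0,3,0,0,3,3,"submetacentric:8"
"Otiorhynchus_bisulcatus",22,14,4,0,0,2,"metacentric","dot-like","Xyp",0,0,NA,0,1,4,4,""
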