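# ordered: 0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,1,0,0,1,1
# outgroup: Otiorhynchus_bisulcatus
"taxon","Number of chromosomes","Presence of B chromosomes","Sex-chromosome system (Xyp)","22 metacentric chromosomes","20 metacentric chromosomes","18 metacentric chromosomes","16 metacentric chromosomes","0 submetacentric chromosomes","2 submetacentric chromosomes","8 submetacentric chromosomes","6 submetacentric chromosomes","4 submetacentric chromosomes","1 telocentric chromosome","Number of the sexual pair","Morphology of the X chromosome","Morphology of the y chromosome","C-band pattern","DAPI distribution","CMA3 distribution","NOR localization (FISH)"
"Sitophilus_zeamais","0","1","1","1","0","0","0","1","0","0","0","0","0","0","1","0","0","0","0","0"
"Sitophilus_oryzae","0","0","1","0","1","0","0","0","1","0","0","0","0","1","1","1","0","0","1","1"
"Sitophilus_granarius","1","0","1","0","0","0","1","0","0","1","0","0","0","2","0","1","1","1","2","2"
"Sitophilus_linearis","1","0","0","0","0","1","0","0","0","1","1","0","1","3","0","2","0","0","3","3"
"Otiorhynchus_bisulcatus","0","0","1","0","0","0","1","0","0","0","0","1","0","?","1","0","0","1","4","4"
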