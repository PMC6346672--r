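fishery,month,catch,n_genotypes,clip_rate
northern_troll,jun,67925,154,0.0164
northern_troll,jul,203773,461,0.0164
northern_troll,aug,67925,153,0.0164
sog_sport,jul,4582,103,0.8393
sog_sport,aug,3054,68,0.8393
worked_example,jul,60,200,0.40
worked_example,aug,20,150,0.40
worked_example,sep,20,0,0.40
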