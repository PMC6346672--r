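population,cwt_catch,cwt_hatchery_escapement,genetic_catch,total_escapement,escapement_clip_rate
Quinsam,1323,3010,1135,3480,0.823
Big Qualicum,1365,4834,1679,6933,0.849
Robertson,4030,5206,3110,9511,0.880
Inch,1879,2781,1488,2779,0.997
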