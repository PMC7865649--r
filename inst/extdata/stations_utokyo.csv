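id,lat,lon
Rec1,35°39′38.12″ N,139°40′54.13″ E
Rec2,35°39′36.19″ N,139°40′55.57″ E
Rec3,35°39′37.63″ N,139°40′57.72″ E
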