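id,lat,lon
A,35°39′37.38″ N,139°40′57.09″ E
B,35°39′36.48″ N,139°40′55.63″ E
C,35°39′37.61″ N,139°40′54.96″ E
D,35°39′37.23″ N,139°40′54.66″ E
E,35°39′37.06″ N,139°40′55.76″ E
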