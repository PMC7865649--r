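call_id,station_id,time_s
E,Rec1,106.416
E,Rec2,106.316
E,Rec3,106.417
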