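id,lat,lon
Rec1,36°56′31.91″ N,139°13′38.43″ E
Rec2,36°56′34.92″ N,139°13′22.63″ E
Rec3,36°56′23.49″ N,139°13′24.27″ E
Rec4,36°56′27.78″ N,139°13′08.86″ E
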