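age_days,a,b,c,v
28.0000,-1.053242766683707421,1.1000000000000001,0.0149999999999999994,-0.2500000000000000000
91.3125,-0.746916537590940344,1.0800000000000001,0.0120000000000000002,-0.1799999999999999933
152.1875,-0.584985205155145960,1.0700000000000001,0.0100000000000000002,-0.1400000000000000133
365.2500,-0.352766948216101106,1.0500000000000000,0.0070000000000000001,-0.0800000000000000017
730.5000,-0.168304931195392471,1.0200000000000000,0.0030000000000000001,-0.0299999999999999989
1095.7500,-0.081888624762258042,1.0100000000000000,0.0020000000000000000,-0.0149999999999999994
1461.0000,-0.024248180130216755,1.0049999999999999,0.0010000000000000000,-0.0050000000000000001
1826.2500,0.000000000000000000,1.0000000000000000,0.0000000000000000000,0.0000000000000000000
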