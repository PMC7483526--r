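date,sunrise_local_min,sunset_local_min
2016-03-20,438.30,1171.10
2016-06-20,274.60,1323.43
2016-06-21,274.82,1323.65
2016-09-22,423.70,1156.24
2016-12-21,583.56,1007.70
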