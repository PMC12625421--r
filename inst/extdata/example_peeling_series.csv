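"x","C_mg_per_kg"
0,32.4855
0.01,28.8086
0.02,26.5081
0.03,23.8216
0.04,20.8271
0.05,17.6311
0.06,15.4366
0.07,11.5656
0.08,9.4875
0.09,5.2434
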