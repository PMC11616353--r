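## table4_sdr.csv

Counts (a,b,c,d): 37, 67, 25, 46; total 175.
OR 1.02 (0.54-1.91), P = 0.96.
X-attributable proportion: 2%.

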