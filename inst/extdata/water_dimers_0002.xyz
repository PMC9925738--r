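6
water_dimers_0002
O  0.0000000000 0.0000000000 0.0000000000
H  0.5858822766 0.7569503273 0.0000000000
H  0.5858822766 -0.7569503273 0.0000000000
O  3.2000000000 0.0000000000 0.0000000000
H  3.7858822766 0.7569503273 0.0000000000
H  3.7858822766 -0.7569503273 0.0000000000
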