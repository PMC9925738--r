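water_dimers_r2.80 water_dimers_0001  1 h2o -2 -13.64625947
water_dimers_r3.20 water_dimers_0002  1 h2o -2 -6.95630159
water_dimers_r4.00 water_dimers_0003  1 h2o -2 -1.76699091
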