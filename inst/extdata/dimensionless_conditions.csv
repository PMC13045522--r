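bioink,concentration,concentration_unit,t20,we,re,oh,fr,l_l_mm,l_ar
fibrinogen,5,mg/mL,0,105.39,1191.5,0.0086,96.278,,3.630
fibrinogen,20,mg/mL,0,95.97,773.0,0.0127,88.803,,
fibrinogen,5,mg/mL,0.001,,,,,,4.098
fibrinogen,20,mg/mL,0.001,107.96,,0.0134,,,
collagen_I,1,mg/mL,0,23.813,95.011,0.051,62.389,,1.725
collagen_I,3,mg/mL,0,,,0.64,,,
collagen_I,7,mg/mL,0,0.895,0.163,5.806,26.713,,0.335
collagen_I,1,mg/mL,0.001,38.061,,0.064,,,2.181
collagen_I,7,mg/mL,0.001,1.303,,6.738,,,0.404
matrigel,0.1,%w/v,0,65.573,637.390,0.0127,86.199,,
matrigel,5,%w/v,0,16.25,,0.096,,,
matrigel,10,%w/v,0,9.310,14.836,0.2057,48.116,0.270,1.079
matrigel,10,%w/v,0.001,14.46,,0.248,,0.336,1.344
alginate,0.05,%w/v,0,65.708,871.11,0.0093,91.147,,
alginate,0.5,%w/v,0,16.452,57.812,0.0702,58.347,,1.434
alginate,0.5,%w/v,0.001,29.600,,0.0915,,,1.924
agarose,0.1,%w/v,0,57.46,510,0.0149,,,0.269
agarose,0.7,%w/v,0,,8.09,0.905,,,0.0044
agarose,0.1,%w/v,0.001,76.62,,0.0172,,,
gelma,0.5,%w/v,0,,254.3,0.0315,,,0.127
gelma,5,%w/v,0,,11.97,0.669,,,0.006
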