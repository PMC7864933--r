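energy_MeV,h
1.03e-09,1
5.78e-09,1
1.87e-08,1
3.28e-08,1
5.78e-08,1
1.03e-07,1
3.28e-07,1
1.03e-06,1
3.28e-06,1
1.03e-05,1
3.28e-05,1
0.000103,1
0.000328,1
0.00103,1
0.00328,1
0.0103,1
0.0328,1
0.0578,1
0.103,1
0.187,1
0.328,1
0.578,1
1.03,1
1.87,1
10.3,1
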