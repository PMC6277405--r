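energy_keV,material,density_g_cm3,mu_total_cm1,mu_compton_cm1
50,water,1.0,0.2269,0.1812
60,water,1.0,0.2059,0.1765
70,water,1.0,0.1929,0.1719
80,water,1.0,0.1837,0.1670
90,water,1.0,0.1763,0.1625
100,water,1.0,0.1707,0.1585
110,water,1.0,0.1658,0.1546
120,water,1.0,0.1614,0.1510
130,water,1.0,0.1573,0.1477
140,water,1.0,0.1537,0.1446
150,water,1.0,0.1505,0.1417
160,water,1.0,0.1476,0.1390
50,lung,0.26,0.0590,0.0471
60,lung,0.26,0.0535,0.0459
70,lung,0.26,0.0502,0.0447
80,lung,0.26,0.0478,0.0434
90,lung,0.26,0.0458,0.0423
100,lung,0.26,0.0444,0.0412
110,lung,0.26,0.0431,0.0402
120,lung,0.26,0.0420,0.0393
130,lung,0.26,0.0409,0.0384
140,lung,0.26,0.0400,0.0376
150,lung,0.26,0.0391,0.0368
160,lung,0.26,0.0384,0.0361
50,air,0.0012,0.000270,0.000216
60,air,0.0012,0.000252,0.000206
70,air,0.0012,0.000237,0.000198
80,air,0.0012,0.000225,0.000190
90,air,0.0012,0.000214,0.000183
100,air,0.0012,0.000205,0.000177
110,air,0.0012,0.000197,0.000171
120,air,0.0012,0.000190,0.000166
130,air,0.0012,0.000184,0.000161
140,air,0.0012,0.000179,0.000157
150,air,0.0012,0.000174,0.000153
160,air,0.0012,0.000170,0.000149
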