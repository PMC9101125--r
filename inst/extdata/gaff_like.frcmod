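GAFF-like starting parameters for fluoro/hydroxy furanoses
MASS

BOND
c3-c3         303.100   1.5350
c3-os         301.500   1.4390
c3-oh         314.100   1.4260
c3-f          363.800   1.3440
c3-h1         335.900   1.0930
ho-oh         369.600   0.9740

ANGLE
c3-c3-c3       63.210    110.630
c3-c3-os       67.780    108.420
c3-c3-oh       67.720    109.430
c3-c3-f        66.220    109.410
c3-c3-h1       46.360    110.050
c3-os-c3       62.010    111.510
c3-oh-ho       47.090    108.160
os-c3-os       68.500    111.550
h1-c3-os       50.840    108.820
h1-c3-oh       50.970    110.260
f-c3-h1        50.900    109.500
f-c3-f         71.260    107.160
f-c3-oh        70.100    108.550
f-c3-os        69.800    108.900
h1-c3-h1       39.180    109.550

DIHE
X-c3-c3-X        1    0.155600     0.000    3.0
X-c3-os-X        1    0.383300     0.000    3.0
X-c3-oh-X        1    0.166700     0.000    3.0
c3-c3-c3-oh      1    0.156000     0.000    3.0
c3-c3-c3-f       1    0.150000     0.000    3.0
c3-c3-oh-ho      1    0.250000     0.000   -1.0
c3-c3-oh-ho      1    0.160000     0.000    3.0
f-c3-c3-f        1    1.200000   180.000   -1.0
f-c3-c3-f        1    0.150000     0.000    3.0
f-c3-c3-oh       1    1.000000   180.000   -1.0
f-c3-c3-oh       1    0.150000     0.000    3.0
f-c3-c3-os       1    1.000000   180.000   -1.0
f-c3-c3-os       1    0.150000     0.000    3.0
oh-c3-c3-oh      1    1.175000     0.000   -2.0
oh-c3-c3-oh      1    0.144000     0.000    3.0

NONBON
  c3       1.9080     0.1094
  os       1.6837     0.1700
  oh       1.7210     0.2104
  ho       0.3000     0.0047
  h1       1.3870     0.0157
  f        1.7500     0.0610

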