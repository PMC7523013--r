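     1     1
    GDAS     1     1     1     0     0
     1 BACKWARD OMEGA
    16     7    15     9   43.916    10.958    135.8
     2 PRESSURE MIXDEPTH
     1     1    16     7    15     9     0     0      0.0   43.916    10.958    135.8    990.0    782.4
     1     1    16     7    15     8     0     0     -1.0   43.887    10.592    176.5    990.0    796.1
     1     1    16     7    15     7     0     0     -2.0   43.804    10.278    163.8    990.0    268.9
     1     1    16     7    15     6     0     0     -3.0   43.888     9.789    136.6    990.0    307.1
     1     1    16     7    15     5     0     0     -4.0   43.901     9.393    139.7    990.0    322.9
     1     1    16     7    15     4     0     0     -5.0   43.997     9.046    135.0    990.0    334.6
     1     1    16     7    15     3     0     0     -6.0   43.929     8.576    118.4    990.0    281.2
     1     1    16     7    15     2     0     0     -7.0   43.954     8.211    162.9    990.0    320.7
     1     1    16     7    15     1     0     0     -8.0   43.993     7.939    166.9    990.0    325.6
     1     1    16     7    15     0     0     0     -9.0   43.981     7.563    147.0    990.0    283.7
     1     1    16     7    14    23     0     0    -10.0   43.941     7.303    152.3    990.0    324.5
     1     1    16     7    14    22     0     0    -11.0   44.019     6.906    138.0    990.0    267.9
     1     1    16     7    14    21     0     0    -12.0   44.042     6.484    149.3    990.0    255.3
     1     1    16     7    14    20     0     0    -13.0   44.114     6.008    134.4    990.0    265.7
     1     1    16     7    14    19     0     0    -14.0   44.128     5.721    173.4    990.0    850.9
     1     1    16     7    14    18     0     0    -15.0   44.024     5.433    136.7    990.0    803.4
     1     1    16     7    14    17     0     0    -16.0   44.023     5.099    151.2    990.0    788.6
     1     1    16     7    14    16     0     0    -17.0   43.978     4.693    162.6    990.0    788.5
     1     1    16     7    14    15     0     0    -18.0   44.018     4.458    151.5    990.0    796.9
     1     1    16     7    14    14     0     0    -19.0   44.018     4.070    154.5    990.0    750.1
     1     1    16     7    14    13     0     0    -20.0   44.091     3.722    132.6    990.0    831.4
     1     1    16     7    14    12     0     0    -21.0   44.121     3.427    174.1    990.0    685.3
     1     1    16     7    14    11     0     0    -22.0   44.047     3.151    133.5    990.0    883.2
     1     1    16     7    14    10     0     0    -23.0   44.014     2.833    137.6    990.0    770.5
     1     1    16     7    14     9     0     0    -24.0   44.080     2.553    168.1    990.0    905.7
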