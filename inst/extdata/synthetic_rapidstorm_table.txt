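# Position-0-0 Position-1-0 ImageNumber-0-0 Amplitude-0-0
582.57 799.32 81 2797.9
1434.94 327.17 916 558.9
1724.75 1871.35 49 1212.3
1900.15 824.33 562 2897.2
1477.68 1925.13 294 2766.0
914.94 1716.40 792 3790.6
1702.86 379.49 681 2456.8
1693.03 316.62 701 3976.0
1134.76 126.21 980 3486.7
913.82 303.64 525 2592.6
1744.80 1108.11 76 2011.2
1976.39 1923.35 179 4862.6
331.77 478.39 898 1937.1
9.46 118.24 961 3395.8
895.12 158.67 872 3057.5
729.43 178.96 495 4980.9
1116.26 1932.89 691 4854.3
1406.71 562.16 86 2046.0
1850.50 1803.02 355 728.1
17.34 1095.46 575 912.2
3.27 18.16 144 2164.0
1752.71 1951.83 298 4200.1
808.13 581.65 385 3528.1
956.74 582.81 832 1762.9
888.20 760.62 332 3233.1
949.31 1873.37 441 4147.6
973.95 453.28 764 2298.2
599.92 1869.41 446 3510.6
1220.38 1114.28 358 4957.6
457.02 1411.50 921 2122.9
1444.91 582.71 497 2370.5
1252.63 1467.09 776 2713.9
1694.30 1127.06 928 2840.9
363.45 1626.79 906 3535.3
1964.91 930.14 339 555.6
875.54 1413.47 723 4678.0
1122.89 1064.66 805 4195.1
1840.41 1058.76 276 4904.1
1638.79 1631.41 937 3982.2
358.51 1158.17 458 3582.8
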