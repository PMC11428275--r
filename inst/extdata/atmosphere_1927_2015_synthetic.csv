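"year","ca","d13c_air"
1927,305.6,-6.7
1928,306.05,-6.72
1929,306.51,-6.74
1930,306.98,-6.759
1931,307.46,-6.779
1932,307.94,-6.799
1933,308.44,-6.819
1934,308.94,-6.838
1935,309.45,-6.858
1936,309.97,-6.878
1937,310.5,-6.898
1938,311.04,-6.918
1939,311.59,-6.937
1940,312.15,-6.957
1941,312.72,-6.977
1942,313.29,-6.997
1943,313.88,-7.016
1944,314.48,-7.036
1945,315.09,-7.056
1946,315.71,-7.076
1947,316.34,-7.095
1948,316.98,-7.115
1949,317.64,-7.135
1950,318.3,-7.155
1951,318.98,-7.175
1952,319.67,-7.194
1953,320.37,-7.214
1954,321.08,-7.234
1955,321.81,-7.254
1956,322.55,-7.273
1957,323.3,-7.293
1958,324.06,-7.313
1959,324.84,-7.333
1960,325.64,-7.352
1961,326.44,-7.372
1962,327.26,-7.392
1963,328.1,-7.412
1964,328.95,-7.432
1965,329.81,-7.451
1966,330.69,-7.471
1967,331.59,-7.491
1968,332.5,-7.511
1969,333.43,-7.53
1970,334.37,-7.55
1971,335.33,-7.57
1972,336.31,-7.59
1973,337.31,-7.61
1974,338.32,-7.629
1975,339.35,-7.649
1976,340.4,-7.669
1977,341.47,-7.689
1978,342.55,-7.708
1979,343.66,-7.728
1980,344.78,-7.748
1981,345.93,-7.768
1982,347.09,-7.787
1983,348.28,-7.807
1984,349.48,-7.827
1985,350.71,-7.847
1986,351.96,-7.867
1987,353.23,-7.886
1988,354.53,-7.906
1989,355.85,-7.926
1990,357.19,-7.946
1991,358.55,-7.965
1992,359.94,-7.985
1993,361.35,-8.005
1994,362.79,-8.025
1995,364.25,-8.045
1996,365.74,-8.064
1997,367.25,-8.084
1998,368.8,-8.104
1999,370.37,-8.124
2000,371.96,-8.143
2001,373.59,-8.163
2002,375.24,-8.183
2003,376.93,-8.203
2004,378.64,-8.222
2005,380.38,-8.242
2006,382.16,-8.262
2007,383.96,-8.282
2008,385.8,-8.302
2009,387.67,-8.321
2010,389.57,-8.341
2011,391.51,-8.361
2012,393.48,-8.381
2013,395.48,-8.4
2014,397.52,-8.42
2015,399.6,-8.44
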