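mu,elevation_m,distance_km,work,slope_index
Spring5_2,713,994,712.9,375.3
Spring4_2,570,392,223.6,726.2
Summer5_2,606,705,464.9,426.1
Summer4_1,350,523,186.5,341.9
Fall4_1,93,112,11.3,409.3
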