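"habitat","season","density","sd"
"grassland_unmanaged","spring",108.6,0.36
"grassland_unmanaged","summer",133.8,0.36
"grassland_unmanaged","autumn",162.6,0.31
"set_aside","spring",56.7,0.31
"set_aside","summer",109.9,0.31
"set_aside","autumn",106.5,0.53
"linear_feature","spring",27.7,0.33
"linear_feature","summer",67.3,0.36
"linear_feature","autumn",77.1,0.57
"pasture_tussocky","spring",15.9,0.43
"pasture_tussocky","summer",50.2,0.48
"pasture_tussocky","autumn",62.7,0.42
"pasture_low_yield","spring",37.1,0.34
"pasture_low_yield","summer",32.4,0.48
"pasture_low_yield","autumn",48.2,0.36
"woodland","spring",4.1,0.37
"woodland","summer",8.2,0.36
"woodland","autumn",8.4,0.47
"field_crop","spring",2.4,0.39
"field_crop","summer",2.4,0.3
"field_crop","autumn",6.4,0.34
"forest_plantation","spring",6,0.37
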