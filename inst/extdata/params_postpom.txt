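V1 = 30
V2 = 23
V3 = 2.1
V4 = 8
V5 = 8
V6 = 9
V7 = 23
V8 = 30
V9 = 0.055
V10 = 0.0025
V11 = 230
V12 = 0.0505
V13 = 4
V14 = 3.552
V15 = 80
V16 = Inf
V17 = 1
weaning_age = 14
gestation_days = 21
litter_mean = 5
lifespan_mean_months = 15
lifespan_sd_months = 3
month_days = 30.44
dispersal_steps = 8
juvenile_range_m = 12
dispersal_step_m = 5
growth_increment = 1
winter_decay = 0.02
encounter_radius = 18
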