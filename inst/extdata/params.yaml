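# Base-case global (non-country-specific) parameters; every key is
# optional and falls back to the package default. See ?global_params.
readmission_cost: 25000        # EUR-2017 per deep-SWI readmission episode
prolonged_mv_fraction: 0.05
prolonged_mv_multiplier: 2
daily_mortality: 0.0005
icu_fraction_of_los: 0.20
icu_mv_share: 0.60
dswi_extra_icu_fraction: 0.30
sswi_extra_icu_fraction: 0
hill_t50: 12                   # days to half-maximal cumulative incidence
hill_n: 2                      # Hill coefficient
horizon_days: 365
extrapolate_incidence: true
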