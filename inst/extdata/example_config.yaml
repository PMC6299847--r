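# Example monitoring-run configuration. Any omitted key keeps its default.
scenario: patient3_like     # or give events_path/vitals_path instead
n_days: 130
seed: 4
condition: COPD             # COPD activates the SpO2 rule; CHF the BP+weight rules
scheme: v2_three_period     # portal alerts only for the all-day period
window_days: 15
k: 2
min_window_obs: 5
persistence_m: 3
min_moves: 30
earliest_cutoff: "05:00"
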