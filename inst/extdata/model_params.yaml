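# Cohort-level model assumptions
cohort_size: 10000
complication_rate: 0.049
risk_cap: 0.5
therapy_efficacy: 0.88
therapy_cost: 2100
complication_cost: 23246
cancellation_rate: 0
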