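# Market prices and epidemiology parameters for the calving-economics trees.
# Keys match the economic_parameters() argument names exactly.
sensor_cost_per_calving: 10
value_male_dairy: 50
value_female_dairy: 100
value_male_cross: 142
value_female_cross: 219
p_male_unsorted: 0.485
p_female_unsorted: 0.516
p_sorted_semen_primi: 0.85
p_beef_semen_pluri: 0.15
sensor_sensitivity: 0.863
p_dystocia_dairy: 0.0375
p_dystocia_cross: 0.085
mort_primi_sensor: 0
mort_pluri_sensor: 0.017
mort_primi_nosensor: 0.11
mort_pluri_nosensor: 0.127
sorted_semen_female_purity: 1.0
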