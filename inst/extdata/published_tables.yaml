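# Published aggregate inputs and results of the Bulgarian degludec vs
# biosimilar glargine U100 short-term cost-utility analysis, transcribed
# verbatim from the source tables. These cells are the calibration targets
# from which the unpublished unit parameters (unit prices, per-event costs,
# disutilities, baseline utilities) are back-derived.
wtp_threshold: 39619
flexible_dosing_utility: 0.006
mortality_risk_severe: 0.0112

# Daily insulin use: observed glargine U100 dose, degludec/glargine dose
# ratio (significance-gated) and the published derived degludec dose.
insulin_use:
  T1DM_BB:
    basal_glargine: 28.11
    basal_ratio: 0.87
    basal_significant: yes
    basal_degludec_printed: 24.46
    bolus_glargine: 37.13
    bolus_ratio: 0.88
    bolus_significant: yes
    bolus_degludec_printed: 32.67
  T2DM_BOT:
    basal_glargine: 28.11
    basal_ratio: 0.90
    basal_significant: yes
    basal_degludec_printed: 25.30
  T2DM_BB:
    basal_glargine: 28.11
    basal_ratio: 1.08
    basal_significant: yes
    basal_degludec_printed: 30.36
    bolus_glargine: 37.13
    bolus_ratio: 1.00
    bolus_significant: no
    bolus_degludec_printed: 37.13

# Hypoglycaemia event rates (events/patient/year): glargine U100 rates,
# degludec/glargine rate ratios (ratio value omitted in the source when not
# significant; recorded here as 1) and the published derived degludec rates.
event_rates:
  T1DM_BB:
    glargine: {daytime: 30.42, nocturnal: 8.52, severe: 3.20}
    ratio:
      daytime: {value: 1.00, significant: no}
      nocturnal: {value: 0.83, significant: yes}
      severe: {value: 1.00, significant: no}
    degludec_printed: {daytime: 30.42, nocturnal: 7.07, severe: 3.20}
  T2DM_BOT:
    glargine: {daytime: 23.12, nocturnal: 13.38, severe: 0.10}
    ratio:
      daytime: {value: 1.00, significant: no}
      nocturnal: {value: 0.64, significant: yes}
      severe: {value: 0.14, significant: yes}
    # the source prints 23.11 for the degludec daytime rate despite a
    # non-significant ratio; treated as a rounding artefact (see vignette)
    degludec_printed: {daytime: 23.11, nocturnal: 8.57, severe: 0.01}
  T2DM_BB:
    glargine: {daytime: 30.42, nocturnal: 8.52, severe: 0.70}
    ratio:
      daytime: {value: 0.83, significant: yes}
      nocturnal: {value: 0.75, significant: yes}
      severe: {value: 1.00, significant: no}
    degludec_printed: {daytime: 25.25, nocturnal: 6.39, severe: 0.70}

# Per-event treatment costs (BGN/event), at 2014 prices and inflated to 2018.
event_cost_per_event:
  cost_2014: {daytime: 0.66, nocturnal: 33.60, severe: 514.36}
  cost_2018: {daytime: 0.65, nocturnal: 33.19, severe: 508.10}

# Annual per-patient costs (BGN/patient/year), QALYs and ICERs (BGN/QALY).
annual_results:
  T1DM_BB:
    insulin: {degludec: 1296.67, glargine: 1180.11, incremental: 116.56}
    hypo_total: {degludec: 1846.61, glargine: 1893.80, incremental: -47.19}
    daytime: {degludec: 19.42, glargine: 19.42, incremental: 0.00}
    nocturnal: {degludec: 230.41, glargine: 277.60, incremental: -47.19}
    severe: {degludec: 1596.78, glargine: 1596.78, incremental: 0.00}
    total: {degludec: 3143.28, glargine: 3073.92, incremental: 69.37}
    qalys: {degludec: 0.5722, glargine: 0.5568, incremental: 0.0154}
    icer: 4498.68
  T2DM_BOT:
    insulin: {degludec: 794.93, glargine: 574.23, incremental: 220.70}
    hypo_total: {degludec: 306.40, glargine: 509.74, incremental: -203.34}
    daytime: {degludec: 15.02, glargine: 15.02, incremental: 0.00}
    nocturnal: {degludec: 284.26, glargine: 443.94, incremental: -159.68}
    severe: {degludec: 7.11, glargine: 50.78, incremental: -43.67}
    total: {degludec: 1101.32, glargine: 1083.97, incremental: 17.35}
    qalys: {degludec: 0.7490, glargine: 0.7055, incremental: 0.0435}
    icer: 399.11
  T2DM_BB:
    insulin: {degludec: 1574.88, glargine: 1196.94, incremental: 377.95}
    hypo_total: {degludec: 581.79, glargine: 655.53, incremental: -73.74}
    daytime: {degludec: 16.35, glargine: 19.69, incremental: -3.35}
    nocturnal: {degludec: 211.17, glargine: 281.56, incremental: -70.39}
    severe: {degludec: 354.28, glargine: 354.28, incremental: 0.00}
    total: {degludec: 2156.67, glargine: 1852.47, incremental: 304.21}
    qalys: {degludec: 0.6893, glargine: 0.6480, incremental: 0.0413}
    icer: 7365.22

# Published one-way scenario ICERs usable as checks (BGN/QALY): the
# no-hypoglycaemia-difference scenario per group.
scenario_icers:
  no_hypoglycaemia_difference: {T2DM_BOT: 36739, T2DM_BB: 63239}
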