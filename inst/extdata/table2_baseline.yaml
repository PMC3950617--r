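# Baseline scenario: fiscal-year average patient flow of a large urban
# hospital. Rates are patients per hour; the transfer fraction is the ratio
# of the ED-to-IU admission rate (0.479/h) to the total ED arrival rate
# (7.572/h).
name: table2_baseline
description: >-
  Hourly CTAS-level ED arrivals plus direct inpatient admissions, with
  triangular ED treatment times (0.1-1 h) and inpatient length of stay
  (1-7 days).
arrivals:
  ctas_1: 0.075
  ctas_2: 0.662
  ctas_3: 3.749
  ctas_4: 2.86
  ctas_5: 0.226
  total: 7.572
  direct_iu: 0.267
transfer_fraction: 0.0632593766508188
ed_service:
  lower: 0.1
  mode: 0.5
  upper: 1.0
  unit: hours
iu_los:
  lower: 1
  mode: 4
  upper: 7
  unit: days
beds:
  ed: 20
  iu: 125
options:
  wait_metric: queueing_delay
  bondi_scaling: scaled
fast_track:
  enabled: false
  fraction: 0.2
  literal_eq14: false
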