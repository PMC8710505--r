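arm: option2
control_rate: 0.69
human_cost: 11938.33
project_cost: 699.4
n_patients: 415
intervention_years: 1.5
lifelong_intervention: yes
transitions:
  p0.5_1: 0.0413
  p0.5_2: 0.0056
  p0.5_3: 0.0016
  p1_0.5: 0.1675
  p1_2: 0.0072
  p1_3: 0.0016
  p2_0.5: 0.0227
  p2_1: 0.0289
  p2_3: 0.0008
  p3_0.5: 0.0060
  p3_1: 0.0060
  p3_2: 0.0008
  p0.5_MI: 0.0014
  p1_MI: 0.0022
  p2_MI: 0.0035
  p3_MI: 0.0035
  p0.5_CHF: 0.0002
  p1_CHF: 0.0003
  p2_CHF: 0.0004
  p3_CHF: 0.0004
  p0.5_Stroke: 0.0011
  p1_Stroke: 0.0020
  p2_Stroke: 0.0035
  p3_Stroke: 0.0035
  p1_ESRD: 0.0152
  p2_ESRD: 0.0078
  p3_ESRD: 0.0017
  pMI_Death: 0.0049
  pCHF_Death: 0.0007
  pStroke_Death: 0.0040
  pESRD_Death: 0.0552
utilities:
  U_pre: 0.651375
  U_1: 0.65525
  U_2: 0.683
  U_3: 0.669
  U_MI: 0.684
  U_Stroke: 0.605
  U_CHF: 0.64
  U_ESRD: 0.60
costs:
  cprehy: 140.69
  chy1: 150.87
  chy2: 187.08
  chy3: 468.15
  cMI: 4953.07
  cStroke: 1974.68
  cCHF: 1754.30
  cESRD: 19406.36
mortality:
  age_lower: [35, 40, 45, 50, 55, 60, 65, 70, 75, 80, 85, 90, 95, 100]
  probability: [0.0012, 0.0018, 0.0026, 0.0042, 0.0062, 0.0103, 0.0172,
    0.0306, 0.0495, 0.0848, 0.1274, 0.1908, 0.2171, 0.4543]
economics:
  discount_rate: 0.05
  wtp: 1599.16
  horizon: 65
  start_age: 35
  cycle_length: 1
  initial_distribution:
    prehypertension: 0.32
    L1: 0.53
    L2: 0.12
    L3: 0.03
  reference_control_rate: 0.61
  half_cycle_correction: no
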