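# Human reference physiology for the MSC PBK model (70 kg adult).
# Units: body_weight_kg [kg], volumes [L], flows [L/h]. Tissue density 1 kg/L.
# Organ weight fractions (lung 0.76, liver 2.57, spleen 0.26, kidney 0.44,
#   heart 0.47 % BW) and flow fractions (liver total 22.7, spleen 1.7,
#   kidney 17.5, heart 4.0 % CO) from the standard reference-man
#   compilations (Brown et al. 1997; Davies & Morris 1993); vascular
#   fractions of organ volume (lung 0.36, liver 0.21, spleen 0.17,
#   kidney 0.16, heart 0.14, rest 0.04); total blood 5.2 L, central
#   arterial pool 25% and central venous pool 50% of total blood.
species: human
body_weight_kg: 70
cardiac_output_L_per_h: 312             # 5.2 L/min
arterial_blood_volume_L: 1.3
venous_blood_volume_L: 2.6
organs:
  lung:
    total_volume_L: 0.532               # 0.76% BW
    vascular_volume_L: 0.19152          # 36% of lung volume
    blood_flow_L_per_h: 312             # total cardiac output
  liver:
    total_volume_L: 1.799               # 2.57% BW
    vascular_volume_L: 0.37779          # 21% of liver volume
    blood_flow_L_per_h: 65.52           # (22.7 - 1.7)% CO; splenic 1.7% arrives via portal link
  spleen:
    total_volume_L: 0.182               # 0.26% BW
    vascular_volume_L: 0.03094          # 17% of spleen volume
    blood_flow_L_per_h: 5.304           # 1.7% CO
  kidney:
    total_volume_L: 0.308               # 0.44% BW
    vascular_volume_L: 0.04928          # 16% of kidney volume
    blood_flow_L_per_h: 54.6            # 17.5% CO
  heart:
    total_volume_L: 0.329               # 0.47% BW
    vascular_volume_L: 0.04606          # 14% of heart volume
    blood_flow_L_per_h: 12.48           # 4.0% CO
  rest_of_body:
    total_volume_L: 62.95               # residual: BW - blood pools - named organs
    vascular_volume_L: 2.518            # 4% of rest-of-body volume
    blood_flow_L_per_h: 174.096         # residual: CO - sum(named systemic flows)
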