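# Rat reference physiology for the MSC PBK model.
# Units: body_weight_kg [kg], volumes [L], flows [L/h]. Tissue density 1 kg/L.
# Organ weight fractions (lung 0.50, liver 3.66, spleen 0.20, kidney 0.73,
#   heart 0.33 % BW), residual-blood fractions (lung 0.50, liver 0.31,
#   spleen 0.17, kidney 0.24, heart 0.26, rest 0.04) and flow fractions
#   (liver total 17.4, spleen 1.0, kidney 14.1, heart 4.9 % CO) from the
#   Brown et al. (1997) compilation; total blood 74 mL/kg; central arterial
#   pool 25% and central venous pool 50% of total blood.
species: rat
body_weight_kg: 0.25
cardiac_output_L_per_h: 4.8             # 80 mL/min for a 250 g rat
arterial_blood_volume_L: 4.625e-3
venous_blood_volume_L: 9.25e-3
organs:
  lung:
    total_volume_L: 1.25e-3             # 0.50% BW
    vascular_volume_L: 6.25e-4          # 50% of lung volume
    blood_flow_L_per_h: 4.8             # total cardiac output
  liver:
    total_volume_L: 9.15e-3             # 3.66% BW
    vascular_volume_L: 2.8365e-3        # 31% of liver volume
    blood_flow_L_per_h: 0.7872          # (17.4 - 1.0)% CO; splenic 1.0% arrives via portal link
  spleen:
    total_volume_L: 5.0e-4              # 0.20% BW
    vascular_volume_L: 8.5e-5           # 17% of spleen volume
    blood_flow_L_per_h: 0.048           # 1.0% CO
  kidney:
    total_volume_L: 1.825e-3            # 0.73% BW
    vascular_volume_L: 4.38e-4          # 24% of kidney volume
    blood_flow_L_per_h: 0.6768          # 14.1% CO
  heart:
    total_volume_L: 8.25e-4             # 0.33% BW
    vascular_volume_L: 2.145e-4         # 26% of heart volume
    blood_flow_L_per_h: 0.2352          # 4.9% CO
  rest_of_body:
    total_volume_L: 2.22575e-1          # residual: BW - blood pools - named organs
    vascular_volume_L: 8.903e-3         # 4% of rest-of-body volume
    blood_flow_L_per_h: 3.0528          # residual: CO - sum(named systemic flows)
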