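# Mouse reference physiology for the MSC PBK model.
# Units: body_weight_kg [kg], volumes [L], flows [L/h]. Tissue density 1 kg/L.
# Organ volumes: fractional organ weights from the Brown et al. (1997)
#   compilation of physiological parameter values (lung 0.73, liver 5.49,
#   spleen 0.35, kidney 1.67, heart 0.50 % of body weight).
# Vascular volumes: residual-blood fractions of organ weight from the same
#   compilation (lung 0.50, liver 0.31, spleen 0.17, kidney 0.24, heart 0.26,
#   rest of body 0.04).
# Blood flows: fractions of cardiac output (liver total 16.1, spleen 1.0,
#   kidney 9.1, heart 6.6 % of CO); lung carries total cardiac output
#   (pulmonary circulation in series); rest_of_body flow is the residual.
#   The liver entry is its arterial-side inflow = total hepatic flow minus
#   the splenic flow that reaches it via the portal link in the topology.
# Total blood volume 77 mL/kg; central arterial pool 25% and central venous
#   pool 50% of total blood, the remainder residing in organ vascular beds.
species: mouse
body_weight_kg: 0.025
cardiac_output_L_per_h: 0.84            # 14 mL/min for a 25 g mouse
arterial_blood_volume_L: 4.8125e-4      # 0.25 x 1.925 mL total blood
venous_blood_volume_L: 9.625e-4         # 0.50 x 1.925 mL total blood
organs:
  lung:
    total_volume_L: 1.825e-4            # 0.73% BW
    vascular_volume_L: 9.125e-5         # 50% of lung volume
    blood_flow_L_per_h: 0.84            # total cardiac output
  liver:
    total_volume_L: 1.3725e-3           # 5.49% BW
    vascular_volume_L: 4.25475e-4       # 31% of liver volume
    blood_flow_L_per_h: 0.12684         # (16.1 - 1.0)% CO; splenic 1.0% arrives via portal link
  spleen:
    total_volume_L: 8.75e-5             # 0.35% BW
    vascular_volume_L: 1.4875e-5        # 17% of spleen volume
    blood_flow_L_per_h: 0.0084          # 1.0% CO
  kidney:
    total_volume_L: 4.175e-4            # 1.67% BW
    vascular_volume_L: 1.002e-4         # 24% of kidney volume
    blood_flow_L_per_h: 0.07644         # 9.1% CO
  heart:
    total_volume_L: 1.25e-4             # 0.50% BW
    vascular_volume_L: 3.25e-5          # 26% of heart volume
    blood_flow_L_per_h: 0.05544         # 6.6% CO
  rest_of_body:
    total_volume_L: 2.137125e-2         # residual: BW - blood pools - named organs
    vascular_volume_L: 8.5485e-4        # 4% of rest-of-body volume
    blood_flow_L_per_h: 0.57288         # residual: CO - sum(named systemic flows)
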