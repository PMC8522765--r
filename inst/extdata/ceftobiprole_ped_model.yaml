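# Final pediatric population PK model for ceftobiprole.
# population_model keys mirror population_model(); rhodin_params keys mirror
# rhodin_params(). Units: clearances L/h, volumes L, GFR ml/min, weight kg.
population_model:
  cl_gfr_slope: 0.0548      # L/h per ml/min of GFR_Rhodin,FFM
  v1_ref: 16.1              # central volume at 70 kg
  q1_ref: 0.545
  vp1_ref: 49.5
  q2_ref: 3.46
  vp2_ref: 6.13
  vol_exponent: 0.911       # fitted weight power shared by V1, Vp1, Vp2
  q_exponent: 0.75          # fixed allometric power for Q1, Q2
  cl_nr: 0.0                # nonrenal clearance fixed to zero
  ref_weight: 70.0
  omega2_cl: 0.0547         # IIV variance on CL (23.4% CV)
  omega2_v1: 0.0711         # IIV variance on V1 (26.7% CV)
  sigma2_prop: 0.0701       # proportional residual variance (26.5% CV)
  sigma2_add: 0.000156      # additive residual variance, SD 0.0125 ug/ml
rhodin_params:
  gfr_std: 121.2            # mature GFR at standard adult FFM, ml/min
  tm50: 47.7                # PMA at half-maturation, weeks
  hill: 3.40
  ffm_ref: 56.1             # FFM of a 70 kg / 176 cm adult male
  size_exponent: 0.75
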