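# Default synthetic-cohort specification, version 1.
#
# Two-group structure of a pulmonary-hypertension referral cohort assessed
# with right-heart catheterisation: group marginals are mean/sd per metric,
# rank correlations couple each metric to catheter mPAP within group via a
# Gaussian copula.  Floors/ceilings are physiologic truncation bounds; the
# generator moment-matches the truncated marginals so the requested
# mean/sd are recovered.
version: 1
groups:
  NO_PH:
    "n": 39
    mpap: {mean: 19, sd: 3, upper: 25}
    lge_rate: 0.064516    # 2/31
    lge_measured_frac: 0.794872   # 31/39
  PH:
    "n": 194
    mpap: {mean: 45, sd: 12, lower: 25}
    lge_rate: 0.843750    # 108/128
    lge_measured_frac: 0.659794   # 128/194
# mean/sd per group; r_mpap is the within-group rank correlation with mPAP.
# Signs follow group physiology (retrograde flow increases with pressure;
# the magnitude is what is specified).
metrics:
  age:           {no_ph: [61, 16],    ph: [63, 15],    r_mpap:  0.00, lower: 18, upper: 95}
  mrap:          {no_ph: [6, 3],      ph: [11, 5],     r_mpap:  0.50, lower: 0}
  co:            {no_ph: [7.0, 1.8],  ph: [5.1, 1.7],  r_mpap: -0.40, lower: 1}
  ci:            {no_ph: [3.7, 0.7],  ph: [2.9, 0.9],  r_mpap: -0.40, lower: 0.5}
  # resistance is strongly right-skewed (sd > mean in the no-PH group), so
  # its marginal is a moment-matched lognormal rather than truncated normal
  pvr:           {no_ph: [149, 167],  ph: [587, 411],  r_mpap:  0.80, dist: lognormal}
  rvedvi:        {no_ph: [77.7, 24.6], ph: [99.1, 39.0], r_mpap: 0.39, lower: 0}
  rv_mass_index: {no_ph: [13.7, 6.92], ph: [37.6, 18.7], r_mpap: 0.74, lower: 0}
  vmi:           {no_ph: [0.26, 0.11], ph: [0.70, 0.35], r_mpap: 0.78, lower: 0}
  rvef:          {no_ph: [39.7, 14.5], ph: [28.2, 14.5], r_mpap: -0.43, lower: 0, upper: 100}
  rvsvi:         {no_ph: [31.4, 13.3], ph: [23.3, 13.2], r_mpap: -0.24, lower: 0}
  tapse:         {no_ph: [2.21, 0.66], ph: [1.55, 0.76], r_mpap: -0.40}
  f_taad:        {no_ph: [24.6, 7.89], ph: [15.9, 7.49], r_mpap: -0.53}
  sfd:           {no_ph: [1.10, 0.45], ph: [0.64, 0.52], r_mpap: -0.46}
  f_sfd:         {no_ph: [27.1, 11.5], ph: [14.4, 12.3], r_mpap: -0.55}
  rvrac:         {no_ph: [39.8, 10.5], ph: [26.2, 13.4], r_mpap: -0.59, upper: 100}
  sei:           {no_ph: [1.19, 0.19], ph: [1.57, 0.52], r_mpap: 0.71, lower: 0.5}
  dei:           {no_ph: [1.17, 0.12], ph: [1.28, 0.23], r_mpap: 0.45, lower: 0.5}
echo_metrics:   # measured in the echocardiography subset only
  trjv:          {no_ph: [2.6, 0.6],  ph: [3.9, 0.9],  r_mpap: 0.74, lower: 0}
phase_contrast_metrics:   # measured in the phase-contrast subset only
  avg_velocity:  {no_ph: [13.6, 6.7], ph: [7.6, 3.4],  r_mpap: -0.55, lower: 0}
  retro_flow:    {no_ph: [0.2, 0.1],  ph: [0.5, 0.3],  r_mpap: 0.33, lower: 0}
  retro_pct:     {no_ph: [9.3, 7.2],  ph: [16.3, 9.2], r_mpap: 0.34, lower: 0}
  pa_rac:        {no_ph: [17.8, 6.6], ph: [8.1, 6.5],  r_mpap: -0.54, lower: 0}
  sys_area:      {no_ph: [7.8, 4.6],  ph: [9.7, 2.8],  r_mpap: 0.28, lower: 1}
  dia_area:      {no_ph: [6.7, 4.7],  ph: [8.9, 2.8],  r_mpap: 0.35, lower: 1}
# PH clinical subgroups (counts; rescaled proportionally when n differs).
# PAH_OTHER pools portal-hypertension and congenital-heart-disease PAH.
subgroups:
  IPAH: 28
  PAH_CTD: 39
  PAH_OTHER: 16
  PH_LHD: 21
  PH_RESP: 29
  CTEPH: 59
# subset sizes over the whole analysed cohort
phase_contrast_frac: 0.454936   # 106/233
echo_frac: 0.836910             # 195/233
female_rate: {NO_PH: 0.56, PH: 0.59}
bsa: {mean: 1.85, sd: 0.20, lower: 1.2, upper: 2.6}
rap_levels: [5, 10, 15]
rap_probs: {NO_PH: [0.8, 0.15, 0.05], PH: [0.35, 0.4, 0.25]}
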