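## Frozen reference parameter set; see ?mcn_parameters for provenance.
## Regenerated by scripts/calibrate.R.
.mcn_defaults <- list(
  k_smpf = 0.0500000000000000,
  v_srum1 = 0.0290000000000000,
  wee1_total = 1.0000000000000000,
  alpha = 0.0500000000000000,
  k_irum1 = 2.0000000000000000,
  k_arum1 = 35.0000000000000000,
  k_drum1p = 250.0000000000000000,
  k_i2rum1 = 50.0000000000000000,
  k_ass = 100.0000000000000000,
  k_diss = 0.0010000000000000,
  k_dx = 1.0000000000000000,
  ccp = 0.0000000000000000,
  af = 0.0000000000000000,
  mu = 0.0050000000000000,
  theta_s = 0.0100000000000000,
  theta_m = 0.2000000000000000,
  k_dmpf = 0.0287534458376835,
  k_dmpf_apc = 0.3031098380068644,
  k_dc = 0.4956934315239646,
  k_dbr = 0.1086446116519598,
  k_wee = 7.8204201629088068,
  k_25 = 12.4333512921738727,
  k_25b = 0.0794544644520930,
  va_wee = 0.9191320567330579,
  vi_wee = 0.8023632163468213,
  va_25 = 2.1723619711186490,
  vi_25 = 0.3697770878517253,
  va_ie = 0.4378971672984733,
  vi_ie = 0.0756796373629444,
  va_apc = 0.9757245010922859,
  vi_apc = 0.0645259811099673,
  j_gk = 0.0100000000000000
)
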