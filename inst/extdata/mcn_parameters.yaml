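# minimal Cdk network parameter set (CU, min)
k_smpf: 0.050000000000000003  # transcribed
v_srum1: 0.029000000000000001  # calibrated
wee1_total: 1  # transcribed
alpha: 0.050000000000000003  # transcribed
k_irum1: 2  # transcribed
k_arum1: 35  # transcribed
k_drum1p: 250  # transcribed
k_i2rum1: 50  # transcribed
k_ass: 100  # derived
k_diss: 0.001  # derived
k_dx: 1  # transcribed
ccp: 0  # transcribed
af: 0  # transcribed
mu: 0.0050000000000000001  # derived
theta_s: 0.01  # transcribed
theta_m: 0.20000000000000001  # transcribed
k_dmpf: 0.028753445837683501  # calibrated
k_dmpf_apc: 0.30310983800686442  # calibrated
k_dc: 0.49569343152396461  # calibrated
k_dbr: 0.10864461165195979  # calibrated
k_wee: 7.8204201629088068  # calibrated
k_25: 12.433351292173873  # calibrated
k_25b: 0.079454464452093004  # calibrated
va_wee: 0.91913205673305787  # calibrated
vi_wee: 0.80236321634682128  # calibrated
va_25: 2.172361971118649  # calibrated
vi_25: 0.36977708785172531  # calibrated
va_ie: 0.43789716729847328  # calibrated
vi_ie: 0.075679637362944405  # calibrated
va_apc: 0.97572450109228592  # calibrated
vi_apc: 0.064525981109967295  # calibrated
j_gk: 0.01  # calibrated
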