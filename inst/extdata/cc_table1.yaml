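lambda_s: 0.0001
lambda_d: 0.001
lambda_e: 1
mu: 9.9999999999999991e-06
v_plus: 0.088888888888888892
v_minus: 0.077777777777777779
D: 0.00098765432098765456
kappa: 10
kappa_0: 10
rho_plus_c: 0.040000000000000001
rho_0_c: 0.040000000000000001
rho_minus_c: 0.040000000000000001
growth_mode: logistic
L: 1
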