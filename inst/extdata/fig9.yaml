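lambda_s: 0.10000000000000001
lambda_d: 0.10000000000000001
lambda_e: 1
mu: 0.10000000000000001
v_plus: 0.10000000000000001
v_minus: 0.050000000000000003
D: 0.001
kappa: 0.20000000000000001
kappa_0: 0.050000000000000003
rho_plus_c: .inf
rho_0_c: .inf
rho_minus_c: .inf
growth_mode: linear
L: 1
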