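dgm: gamma_lagged_y
n_individuals: 200
lambda: 0.1
p: 1.05
beta: 1.0
alpha0: 0.0
alpha1: 1.0
alpha2: 0.2
gamma_assoc: 0.0
sigma2_u: 1.0
sigma2_v: 0.5
sigma2_eps: 1.0
psi: 2.0
omega: 0.2
sigma2_xi: 0.1
gamma_shape: 2.0
censor_lo: 5.0
censor_hi: 10.0
regular_interval: 1.0
treatment_prob: 0.5
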