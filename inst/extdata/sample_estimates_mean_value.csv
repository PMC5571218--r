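parameter,sample,value
k_IL,1,0.25
k_IL,2,0.00
k_IL,3,0.03
k_IL,4,0.29
k_IL,5,0.22
k_E,1,0.23
k_E,2,0.28
k_E,3,0.21
k_E,4,0.21
k_E,5,0.28
k_C,1,10.5
k_C,2,16.9
k_C,3,10.7
k_C,4,42.7
k_C,5,36.1
M_C,1,5.66
M_C,2,5.66
M_C,3,5.71
M_C,4,5.31
M_C,5,5.13
e_01,1,0.23
e_01,2,0.30
e_01,3,0.29
e_01,4,0.22
e_01,5,0.24
e_02,1,0.39
e_02,2,0.21
e_02,3,0.38
e_02,4,0.36
e_02,5,0.26
mu_E1,1,0.23
mu_E1,2,0.31
mu_E1,3,0.36
mu_E1,4,0.23
mu_E1,5,0.20
mu_E2,1,1.70
mu_E2,2,1.62
mu_E2,3,1.81
mu_E2,4,1.63
mu_E2,5,1.90
mu_C1,1,0.38
mu_C1,2,0.30
mu_C1,3,0.33
mu_C1,4,0.40
mu_C1,5,0.32
mu_C2,1,1.76
mu_C2,2,1.85
mu_C2,3,1.74
mu_C2,4,1.70
mu_C2,5,1.77
mu_M,1,0.27
mu_M,2,0.21
mu_M,3,0.26
mu_M,4,0.15
mu_M,5,0.19
rho1,1,0.48
rho1,2,0.36
rho1,3,0.53
rho1,4,0.27
rho1,5,0.24
rho2,1,1.80
rho2,2,1.57
rho2,3,1.73
rho2,4,1.47
rho2,5,1.27
lam_max,1,1.48
lam_max,2,1.22
lam_max,3,1.48
lam_max,4,1.47
lam_max,5,1.48
sigma_max,1,0.08
sigma_max,2,0.10
sigma_max,3,0.08
sigma_max,4,0.08
sigma_max,5,0.12
tau,1,0.13
tau,2,0.14
tau,3,0.24
tau,4,0.17
tau,5,0.38
k_smc,1,0.01
k_smc,2,0.00
k_smc,3,0.00
k_smc,4,0.03
k_smc,5,0.01
mu_SMC,1,0.26
mu_SMC,2,0.23
mu_SMC,3,0.27
mu_SMC,4,0.20
mu_SMC,5,0.12
r2_pressure_full,1,0.93
r2_pressure_full,2,0.90
r2_pressure_full,3,0.86
r2_pressure_full,4,0.99
r2_pressure_full,5,0.99
r2_force_full,1,0.84
r2_force_full,2,0.63
r2_force_full,3,0.70
r2_force_full,4,0.96
r2_force_full,5,0.85
r2_radius_full,1,0.96
r2_radius_full,2,0.86
r2_radius_full,3,0.79
r2_radius_full,4,0.96
r2_radius_full,5,0.89
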