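parameter,sample,value
k_IL,1,0.15
k_IL,2,0.04
k_IL,3,0.04
k_IL,4,0.28
k_IL,5,0.39
k_E,1,0.30
k_E,2,0.28
k_E,3,0.14
k_E,4,0.28
k_E,5,0.35
k_C,1,11.8
k_C,2,55.1
k_C,3,10.9
k_C,4,57.9
k_C,5,11.8
M_C,1,5.68
M_C,2,5.65
M_C,3,5.91
M_C,4,5.58
M_C,5,3.32
e_02,1,0.39
e_02,2,0.38
e_02,3,0.37
e_02,4,0.38
e_02,5,0.25
alpha1,1,8.30
alpha1,2,4.97
alpha1,3,4.90
alpha1,4,5.22
alpha1,5,6.97
alpha2,1,71.9
alpha2,2,42.0
alpha2,3,47.7
alpha2,4,67.2
alpha2,5,71.0
mu_E1,1,0.32
mu_E1,2,0.20
mu_E1,3,0.20
mu_E1,4,0.24
mu_E1,5,0.29
sd_E1,1,0.26
sd_E1,2,0.10
sd_E1,3,0.14
sd_E1,4,0.12
sd_E1,5,0.24
mu_E2,1,1.74
mu_E2,2,1.97
mu_E2,3,1.80
mu_E2,4,1.96
mu_E2,5,1.71
sd_E2,1,0.56
sd_E2,2,0.46
sd_E2,3,0.26
sd_E2,4,0.33
sd_E2,5,0.30
mu_C1,1,0.20
mu_C1,2,0.37
mu_C1,3,0.38
mu_C1,4,0.38
mu_C1,5,0.26
sd_C1,1,0.30
sd_C1,2,0.15
sd_C1,3,0.27
sd_C1,4,0.16
sd_C1,5,0.27
mu_C2,1,2.09
mu_C2,2,2.08
mu_C2,3,1.58
mu_C2,4,1.61
mu_C2,5,1.71
sd_C2,1,0.22
sd_C2,2,0.44
sd_C2,3,0.28
sd_C2,4,0.24
sd_C2,5,0.47
mu_M,1,0.29
mu_M,2,0.18
mu_M,3,0.28
mu_M,4,0.13
mu_M,5,0.26
sd_M,1,0.30
sd_M,2,0.11
sd_M,3,0.13
sd_M,4,0.16
sd_M,5,0.27
rho1,1,0.27
rho1,2,0.30
rho1,3,0.47
rho1,4,0.25
rho1,5,0.27
rho2,1,1.04
rho2,2,1.83
rho2,3,1.66
rho2,4,1.83
rho2,5,0.79
lam_max,1,1.45
lam_max,2,1.28
lam_max,3,1.48
lam_max,4,1.35
lam_max,5,1.16
sigma_max,1,0.08
sigma_max,2,0.09
sigma_max,3,0.08
sigma_max,4,0.07
sigma_max,5,0.11
tau,1,0.32
tau,2,0.11
tau,3,0.15
tau,4,0.26
tau,5,0.30
k_smc,1,0.03
k_smc,2,0.00
k_smc,3,0.00
k_smc,4,0.03
k_smc,5,0.01
mu_SMC,1,0.19
mu_SMC,2,0.27
mu_SMC,3,0.22
mu_SMC,4,0.25
mu_SMC,5,0.29
sd_SMC,1,0.15
sd_SMC,2,0.29
sd_SMC,3,0.29
sd_SMC,4,0.12
sd_SMC,5,0.22
r2_pressure_full,1,0.95
r2_pressure_full,2,0.85
r2_pressure_full,3,0.99
r2_pressure_full,4,0.99
r2_pressure_full,5,0.94
r2_force_full,1,0.83
r2_force_full,2,0.83
r2_force_full,3,0.77
r2_force_full,4,0.93
r2_force_full,5,0.79
r2_radius_full,1,0.96
r2_radius_full,2,0.93
r2_radius_full,3,0.87
r2_radius_full,4,0.95
r2_radius_full,5,0.98
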