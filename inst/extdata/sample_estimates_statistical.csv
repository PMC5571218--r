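parameter,sample,value
k_IL,1,0.19
k_IL,2,0.05
k_IL,3,0.02
k_IL,4,0.23
k_IL,5,0.17
k_E,1,0.25
k_E,2,0.28
k_E,3,0.13
k_E,4,0.13
k_E,5,0.26
k_C,1,10.0
k_C,2,48.2
k_C,3,10.9
k_C,4,100
k_C,5,36.4
M_C,1,5.96
M_C,2,5.71
M_C,3,6.00
M_C,4,5.99
M_C,5,4.06
rho1,1,0.47
rho1,2,0.45
rho1,3,0.63
rho1,4,0.20
rho1,5,0.30
rho2,1,1.22
rho2,2,0.59
rho2,3,0.03
rho2,4,1.66
rho2,5,0.90
lam_max,1,1.44
lam_max,2,1.06
lam_max,3,1.39
lam_max,4,1.38
lam_max,5,1.36
sigma_max,1,0.10
sigma_max,2,0.11
sigma_max,3,0.07
sigma_max,4,0.06
sigma_max,5,0.12
tau,1,0.14
tau,2,0.20
tau,3,0.45
tau,4,0.87
tau,5,0.13
k_smc,1,0.12
k_smc,2,0.00
k_smc,3,0.003
k_smc,4,0.02
k_smc,5,0.002
r2_pressure_passive,1,0.80
r2_pressure_passive,2,0.96
r2_pressure_passive,3,0.95
r2_pressure_passive,4,0.96
r2_pressure_passive,5,0.96
r2_force_passive,1,0.78
r2_force_passive,2,0.77
r2_force_passive,3,0.82
r2_force_passive,4,0.72
r2_force_passive,5,0.86
r2_radius_passive,1,0.91
r2_radius_passive,2,0.91
r2_radius_passive,3,0.96
r2_radius_passive,4,0.93
r2_radius_passive,5,0.94
r2_pressure_full,1,0.83
r2_pressure_full,2,0.69
r2_pressure_full,3,0.99
r2_pressure_full,4,0.99
r2_pressure_full,5,0.83
r2_force_full,1,0.71
r2_force_full,2,0.77
r2_force_full,3,0.72
r2_force_full,4,0.78
r2_force_full,5,0.86
r2_radius_full,1,0.90
r2_radius_full,2,0.58
r2_radius_full,3,0.85
r2_radius_full,4,0.91
r2_radius_full,5,0.91
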