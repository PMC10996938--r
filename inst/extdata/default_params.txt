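# chromaCSF model parameter file
ach.sustained.beta 1.3
ach.sustained.sigma 100
ach.sustained.k_rho1 4
ach.sustained.k_rho2 1.5
ach.sustained.k_rho3 0.40000000000000002
ach.sustained.k_b 0.80000000000000004
ach.sustained.k_a 0.69999999999999996
ach.sustained.a0 2.5
ach.sustained.rho0 0.5
ach.sustained.ks1 300
ach.sustained.ks2 30
ach.sustained.ks3 0.80000000000000004
ach.sustained.ks4 7000
ach.sustained.ks5 1
ach.transient.beta 1.5
ach.transient.sigma 150
ach.transient.m_omega 2.5
ach.transient.c_omega 5
ach.transient.k_rho 0.10000000000000001
ach.transient.k_b 1.2
ach.transient.k_a 0.5
ach.transient.a0 10
ach.transient.rho0 2
ach.transient.ks1 0.34999999999999998
ach.transient.ks2 15
ach.ecc.ke1 0.02
ach.ecc.ke2 0.02
ach.ecc.ke1_nasal 0.014999999999999999
ach.ecc.ke2_nasal 0.01
rg.sustained.beta 1.2
rg.sustained.sigma 30
rg.sustained.k_rho 0.5
rg.sustained.k_b 1.2
rg.sustained.a0 40
rg.sustained.rho0 0.10000000000000001
rg.sustained.ks1 2000
rg.sustained.ks2 30
rg.sustained.ks3 0.69999999999999996
rg.ecc.ke1 0.01
rg.ecc.ke2 0.035000000000000003
rg.ecc.ke1_nasal 0.0080000000000000002
rg.ecc.ke2_nasal 0.029999999999999999
yv.sustained.beta 1.2
yv.sustained.sigma 20
yv.sustained.k_rho 0.40000000000000002
yv.sustained.k_b 1.2
yv.sustained.a0 60
yv.sustained.rho0 0.080000000000000002
yv.sustained.ks1 150
yv.sustained.ks2 30
yv.sustained.ks3 0.69999999999999996
yv.ecc.ke1 0.014999999999999999
yv.ecc.ke2 0.02
yv.ecc.ke1_nasal 0.012
yv.ecc.ke2_nasal 0.014999999999999999
disc.beta 3.0114200000000002
disc.a_disc 2.4243700000000001
options.bandwidth_mode pow2
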