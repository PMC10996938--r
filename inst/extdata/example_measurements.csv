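dataset_id,L0,M0,S0,dL,dM,dS,rho_cpd,omega_hz,area_deg2,ecc_deg,theta_deg,shape,sensitivity
demo-gabor,20.49,9.51,0.78,20.49,9.51,0,1,0,3.14,0,0,gabor,112.4
demo-gabor,20.49,9.51,0.78,1,-1,0,4,0,3.14,0,0,gabor,148.9
demo-gabor,20.49,9.51,0.78,0,0,1,0.5,8,3.14,0,0,gabor,95.3
demo-disc,68.3,31.7,2.61,0,0,1,,0,3.14,10,180,disc,61.7
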