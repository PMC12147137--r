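name,delta_omega_ppm,f,k_ex_s,t1_free_s,t2_free_s,t1_bound_s,t2_bound_s
La,0.8,0.005,800,2.5,0.9,2.5,0.02
Ce,-1.8,0.005,900,2.3,0.8,2.3,0.02
Pr,-3.1,0.005,1100,2.2,0.7,2.2,0.02
Nd,-1.2,0.005,1000,2.2,0.75,2.2,0.02
Sm,-0.6,0.005,1200,2.4,0.85,2.4,0.02
Eu,1.1,0.005,1300,2.3,0.8,2.3,0.02
Gd,0.3,0.005,1500,0.6,0.08,0.1,0.002
Tb,-24.6,0.005,1700,1.6,0.35,1.6,0.02
Dy,-28.6,0.005,1800,1.5,0.3,1.5,0.02
Ho,-11.2,0.005,1600,1.7,0.4,1.7,0.02
Er,9.4,0.005,1400,1.8,0.45,1.8,0.02
Tm,15.2,0.005,1200,1.9,0.5,1.9,0.02
Yb,6.3,0.005,1000,2.1,0.65,2.1,0.02
Lu,1.4,0.005,700,2.5,0.9,2.5,0.02
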