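trial,theta_alpha,optimal_iteration,qubit_init,best_fitness,s
1,0.25,15,0.55,0.0210,0.4
2,0.30,30,0.60,0.0250,0.3
3,0.35,45,0.65,0.0310,0.3
4,0.40,60,0.70,0.0180,0.5
5,0.45,75,0.75,0.0290,0.4
6,0.50,90,0.80,0.0340,0.2
7,0.55,105,0.85,0.0270,0.5
8,0.60,120,0.90,0.0220,0.4
9,0.55,135,0.95,0.0260,0.3
10,0.70,150,1.00,0.0300,0.6
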