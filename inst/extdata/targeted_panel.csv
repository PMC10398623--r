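name,formula,rt,rf,recovery_pct,mdl
syringic acid,C9H10O5,9.05,1.1,62,0.005
vanillic acid,C8H8O4,8.94,1.0,69,0.012
vanillin,C8H8O3,9.22,1.02,67,0.007
syringaldehyde,C9H10O4,9.30,0.85,78,0.003
p-hydroxybenzoic acid,C7H6O3,8.58,3.8,81,0.007
pinic acid,C9H14O4,9.03,2.2,87,0.010
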