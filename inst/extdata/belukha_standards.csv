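name,formula,rt
succinic acid,C4H6O4,3.88
azelaic acid,C9H16O4,10.41
glutaric acid,C5H8O4,4.53
3-methylglutaric acid,C6H10O4,6.71
methylsuccinic acid,C5H8O4,5.70
levulinic acid,C5H8O3,4.04
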