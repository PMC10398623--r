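id,mz,rt,area,sample,library_score
B01,117.01934,3.89,2.53e9,belukha_1934,87.2
B02,171.06640,7.51,1.50e9,belukha_1934,
B03,157.05066,7.98,1.39e9,belukha_1934,
B04,187.09764,10.42,6.40e8,belukha_1934,92.8
B05,131.03498,4.58,5.00e8,belukha_1934,93.2
B06,145.05069,8.19,4.79e8,belukha_1934,87.5
B07,131.03497,5.86,4.18e8,belukha_1934,94.6
B08,115.04009,4.08,3.73e8,belukha_1934,89.8
B09,183.10267,9.70,3.26e8,belukha_1934,
B10,201.07705,7.82,3.14e8,belukha_1934,
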