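# Synthetic stand-in for a pod-length GWAS hit list: 55 mapped SNPs on 9
# linkage groups arranged in 16 LD-block clusters (consecutive intra-cluster
# gaps < 2 cM, inter-cluster gaps > 2 cM). Generated, not measured data.
# trait: pod length; mode: gwas
snp_id	lg	cm
PLS_LG01_c01_1	LG01	11.5
PLS_LG01_c01_2	LG01	11.71
PLS_LG01_c01_3	LG01	12.3
PLS_LG01_c01_4	LG01	13.19
PLS_LG01_c01_5	LG01	14.69
PLS_LG01_c01_6	LG01	15.49
PLS_LG01_c01_7	LG01	16.2
PLS_LG01_c01_8	LG01	17.57
PLS_LG02_c02_1	LG02	12.16
PLS_LG02_c02_2	LG02	13.02
PLS_LG02_c02_3	LG02	14.42
PLS_LG02_c02_4	LG02	15.26
PLS_LG02_c02_5	LG02	15.6
PLS_LG02_c02_6	LG02	17.15
PLS_LG03_c03_1	LG03	12.24
PLS_LG03_c03_2	LG03	13.4
PLS_LG03_c03_3	LG03	13.63
PLS_LG03_c03_4	LG03	14.04
PLS_LG03_c03_5	LG03	15.41
PLS_LG03_c04_1	LG03	19.68
PLS_LG03_c04_2	LG03	20.65
PLS_LG03_c04_3	LG03	20.97
PLS_LG03_c04_4	LG03	21.79
PLS_LG03_c04_5	LG03	22.58
PLS_LG04_c05_1	LG04	11.92
PLS_LG04_c05_2	LG04	13.28
PLS_LG04_c05_3	LG04	14.82
PLS_LG04_c05_4	LG04	16.03
PLS_LG05_c06_1	LG05	7.06
PLS_LG05_c06_2	LG05	8.13
PLS_LG05_c06_3	LG05	9.46
PLS_LG05_c06_4	LG05	9.73
PLS_LG05_c07_1	LG05	18.09
PLS_LG05_c07_2	LG05	18.53
PLS_LG05_c07_3	LG05	18.93
PLS_LG05_c07_4	LG05	19.25
PLS_LG05_c16_1	LG05	28.44
PLS_LG07_c08_1	LG07	14.49
PLS_LG07_c08_2	LG07	16.05
PLS_LG07_c08_3	LG07	17.09
PLS_LG07_c09_1	LG07	24.96
PLS_LG07_c09_2	LG07	26.08
PLS_LG07_c09_3	LG07	26.31
PLS_LG08_c10_1	LG08	6.22
PLS_LG08_c10_2	LG08	7.21
PLS_LG08_c10_3	LG08	7.87
PLS_LG08_c11_1	LG08	17.64
PLS_LG08_c11_2	LG08	19.23
PLS_LG09_c12_1	LG09	7.65
PLS_LG09_c12_2	LG09	8.79
PLS_LG09_c13_1	LG09	16.2
PLS_LG09_c13_2	LG09	16.88
PLS_LG11_c14_1	LG11	9.78
PLS_LG11_c14_2	LG11	10.4
PLS_LG11_c15_1	LG11	21.45
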