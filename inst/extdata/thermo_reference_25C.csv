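fragment,n_value,n_sd,kd_nm,kd_sd_nm,dh,dh_sd,tds_neg,tds_sd,dg,dg_sd
151-335,1.10,0.06,540,40,-52.3,0.8,16.5,1.0,-35.8,0.2
195-276,1.09,0.02,450,30,-51.2,0.6,15.0,0.7,-36.2,0.2
234-335,1.0,0.2,440,60,-58,1,22,2,-36.3,0.3
234-276_ABS-RIM,0.98,0.08,510,20,-50.7,0.3,14.8,0.4,-35.9,0.1
234-272,0.97,0.05,1800,400,-43,3,10,4,-32.8,0.5
234-256_ABS,0.86,0.03,6000,200,-54.0,0.5,24.2,0.6,-29.8,0.1
255-276_RIM,NA,NA,5000000,NA,NA,NA,NA,NA,NA,NA
195-335_d244-276,1.02,0.09,5400,600,-59,2,28,2,-30.1,0.3
195-276_L237A,1.03,0.06,2400,300,-22.9,0.7,-9.2,0.9,-32.1,0.3
195-276_V239A,0.95,0.01,2000,200,-42,1,10,1,-32.5,0.3
195-276_D241A,1.07,0.06,2000,700,-37,7,5,7,-32.5,0.9
195-276_Y242A,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
195-276_W244A,1.0,0.1,1900,200,-47,1,14,2,-32.7,0.3
234-276_P245A,1.26,0.01,780,60,-43.4,0.8,8.8,0.8,-34.9,0.2
195-276_F259A,1.2,0.1,550,50,-58.8,0.9,23,1,-35.8,0.2
195-276_E263P,1.00,0.06,580,40,-61.2,0.8,25.5,1.0,-35.6,0.2
195-276_F274A,0.86,0.02,660,90,-62,2,27,2,-35.3,0.3
ACID_R568A,0.90,0.01,3100,700,-46,4,14,5,-31.5,0.5
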