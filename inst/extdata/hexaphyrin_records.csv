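key,state,pattern,choices,phi_p,pi_index,lambda_exalt,nics_zz1,av1245,av_min,delta_eta,delta_hl,beta_hrs_static,beta_hrs_0653,beta_hrs_1165,symmetry,provenance
26D(H),26D,FULL,H,6.41,0.99,-184,-22.4,1.80,0.77,3.77,3.71,1828,3512,4069,C1,Table 1
26R(H),26R,FULL,H,11.66,0.88,-155,-15.8,1.68,0.66,1.79,3.66,2347,5432,6570,C1,Table 1
28R(H),28R,FULL,H,10.87,0.90,239,41.2,1.33,0.42,-11.54,3.00,0,0,0,Ci,Table 1
28M(H),28M,FULL,H,31.54,-0.45,-92,-10.7,1.63,0.79,1.68,3.82,1470,2311,5679,C1,Table 1
26R(F),26R,FULL,F,8.83,0.90,,,,,,3.23,8620,,,unknown,Table 2
28R(F),28R,FULL,F,11.01,0.90,,,,,,3.11,0,,,Ci,Table 2
28M(F),28M,FULL,F,32.55,-0.46,,,,,,3.42,2090,,,unknown,Table 2
26R(CN),26R,FULL,CN,12.69,0.88,,,,,,3.63,1640,,,unknown,Table 2
28R(CN),28R,FULL,CN,27.98,0.54,,,,,,3.05,1170,,,unknown,Table 2
28M(CN),28M,FULL,CN,32.38,-0.46,,,,,,3.63,1540,,,unknown,Table 2
26R(NO2),26R,FULL,NO2,15.61,0.79,,,,,,3.83,1460,,,unknown,Table 2
28R(NO2),28R,FULL,NO2,40.58,0.18,,,,,,3.66,1020,,,unknown,Table 2
28M(NO2),28M,FULL,NO2,34.20,-0.43,,,,,,3.64,2280,,,unknown,Table 2
26R(PhF5),26R,FULL,PhF5,16.31,0.80,,,,,,3.64,3180,,,unknown,Table 2
28R(PhF5),28R,FULL,PhF5,47.95,0.47,,,,,,3.28,1860,,,unknown,Table 2
28M(PhF5),28M,FULL,PhF5,32.91,-0.38,,,,,,3.68,1750,,,unknown,Table 2
26R(CH3),26R,FULL,CH3,18.11,0.66,,,,,,1.57,29600,,,unknown,Table 2
28R(CH3),28R,FULL,CH3,21.91,0.68,,,,,,3.18,0,,,Ci,Table 2
28M(CH3),28M,FULL,CH3,32.59,-0.46,,,,,,3.68,1160,,,unknown,Table 2
26R(NH2),26R,FULL,NH2,29.26,0.53,,,,,,2.52,33700,,,unknown,Table 2
28R(NH2),28R,FULL,NH2,30.71,0.43,,,,,,3.33,2700,,,unknown,Table 2
28M(NH2),28M,FULL,NH2,33.23,-0.45,,,,,,3.62,2210,,,unknown,Table 2
26R(OH),26R,FULL,OH,14.28,0.86,,,,,,2.56,25700,,,unknown,Table 2
28R(OH),28R,FULL,OH,14.26,0.80,,,,,,3.08,0,,,Ci,Table 2
28M(OH),28M,FULL,OH,32.52,-0.45,,,,,,3.29,2890,,,unknown,Table 2
26R(F_H_H),26R,A2B2C2,F_H_H,,,,,,,,,5060,,,unknown,Table 3
26R(H_F_H),26R,A2B2C2,H_F_H,,,,,,,,,2950,,,unknown,Table 3
26R(H_H_F),26R,A2B2C2,H_H_F,,,,,,,,,4630,,,unknown,Table 3
28R(F_H_H),28R,A2B2C2,F_H_H,,,,,,,,,0,,,Ci,Table 3
28R(H_F_H),28R,A2B2C2,H_F_H,,,,,,,,,0,,,Ci,Table 3
28R(H_H_F),28R,A2B2C2,H_H_F,,,,,,,,,0,,,Ci,Table 3
28M(F_H_H),28M,A2B2C2,F_H_H,,,,,,,,,354,,,unknown,Table 3
28M(H_F_H),28M,A2B2C2,H_F_H,,,,,,,,,1700,,,unknown,Table 3
28M(H_H_F),28M,A2B2C2,H_H_F,,,,,,,,,1170,,,unknown,Table 3
26R(CN_H_H),26R,A2B2C2,CN_H_H,,,,,,,,,1200,,,unknown,Table 3
26R(H_CN_H),26R,A2B2C2,H_CN_H,,,,,,,,,6380,,,unknown,Table 3
26R(H_H_CN),26R,A2B2C2,H_H_CN,,,,,,,,,2450,,,unknown,Table 3
28R(CN_H_H),28R,A2B2C2,CN_H_H,,,,,,,,,0,,,Ci,Table 3
28R(H_CN_H),28R,A2B2C2,H_CN_H,,,,,,,,,0,,,Ci,Table 3
28R(H_H_CN),28R,A2B2C2,H_H_CN,,,,,,,,,0,,,Ci,Table 3
28M(CN_H_H),28M,A2B2C2,CN_H_H,,,,,,,,,1960,,,unknown,Table 3
28M(H_CN_H),28M,A2B2C2,H_CN_H,,,,,,,,,1530,,,unknown,Table 3
28M(H_H_CN),28M,A2B2C2,H_H_CN,,,,,,,,,554,,,unknown,Table 3
26R(NO2_H_H),26R,A2B2C2,NO2_H_H,,,,,,,,,1140,,,unknown,Table 3
26R(H_NO2_H),26R,A2B2C2,H_NO2_H,,,,,,,,,4140,,,unknown,Table 3
26R(H_H_NO2),26R,A2B2C2,H_H_NO2,,,,,,,,,1520,,,unknown,Table 3
28R(NO2_H_H),28R,A2B2C2,NO2_H_H,,,,,,,,,1340,,,C2,Table 3
28R(H_NO2_H),28R,A2B2C2,H_NO2_H,,,,,,,,,0,,,Ci,Table 3
28R(H_H_NO2),28R,A2B2C2,H_H_NO2,,,,,,,,,923,,,C2,Table 3
28M(NO2_H_H),28M,A2B2C2,NO2_H_H,,,,,,,,,2900,,,unknown,Table 3
28M(H_NO2_H),28M,A2B2C2,H_NO2_H,,,,,,,,,2550,,,unknown,Table 3
28M(H_H_NO2),28M,A2B2C2,H_H_NO2,,,,,,,,,2010,,,unknown,Table 3
26R(CH3_H_H),26R,A2B2C2,CH3_H_H,,,,,,,,,3210,,,unknown,Table 3
26R(H_CH3_H),26R,A2B2C2,H_CH3_H,,,,,,,,,3870,,,unknown,Table 3
26R(H_H_CH3),26R,A2B2C2,H_H_CH3,,,,,,,,,3460,,,unknown,Table 3
28R(CH3_H_H),28R,A2B2C2,CH3_H_H,,,,,,,,,0,,,Ci,Table 3
28R(H_CH3_H),28R,A2B2C2,H_CH3_H,,,,,,,,,0,,,Ci,Table 3
28R(H_H_CH3),28R,A2B2C2,H_H_CH3,,,,,,,,,0,,,Ci,Table 3
28M(CH3_H_H),28M,A2B2C2,CH3_H_H,,,,,,,,,458,,,unknown,Table 3
28M(H_CH3_H),28M,A2B2C2,H_CH3_H,,,,,,,,,422,,,unknown,Table 3
28M(H_H_CH3),28M,A2B2C2,H_H_CH3,,,,,,,,,900,,,unknown,Table 3
26R(OH_H_H),26R,A2B2C2,OH_H_H,,,,,,,,,9990,,,unknown,Table 3
26R(H_OH_H),26R,A2B2C2,H_OH_H,,,,,,,,,3610,,,unknown,Table 3
26R(H_H_OH),26R,A2B2C2,H_H_OH,,,,,,,,,8920,,,unknown,Table 3
28R(OH_H_H),28R,A2B2C2,OH_H_H,,,,,,,,,0,,,Ci,Table 3
28R(H_OH_H),28R,A2B2C2,H_OH_H,,,,,,,,,0,,,Ci,Table 3
28R(H_H_OH),28R,A2B2C2,H_H_OH,,,,,,,,,0,,,Ci,Table 3
28M(OH_H_H),28M,A2B2C2,OH_H_H,,,,,,,,,895,,,unknown,Table 3
28M(H_OH_H),28M,A2B2C2,H_OH_H,,,,,,,,,1610,,,unknown,Table 3
28M(H_H_OH),28M,A2B2C2,H_H_OH,,,,,,,,,2130,,,unknown,Table 3
26R(NH2_H_H),26R,A2B2C2,NH2_H_H,,,,,,,,,15600,,,unknown,Table 3
26R(H_NH2_H),26R,A2B2C2,H_NH2_H,,,,,,,,,2740,,,unknown,Table 3
26R(H_H_NH2),26R,A2B2C2,H_H_NH2,,,,,,,,,11400,,,unknown,Table 3
28R(NH2_H_H),28R,A2B2C2,NH2_H_H,,,,,,,,,0,,,Ci,Table 3
28R(H_NH2_H),28R,A2B2C2,H_NH2_H,,,,,,,,,0,,,Ci,Table 3
28R(H_H_NH2),28R,A2B2C2,H_H_NH2,,,,,,,,,1280,,,C2,Table 3
28M(NH2_H_H),28M,A2B2C2,NH2_H_H,,,,,,,,,963,,,unknown,Table 3
28M(H_NH2_H),28M,A2B2C2,H_NH2_H,,,,,,,,,2050,,,unknown,Table 3
28M(H_H_NH2),28M,A2B2C2,H_H_NH2,,,,,,,,,1360,,,unknown,Table 3
26R(NH2_OH_NH2),26R,A2B2C2,NH2_OH_NH2,13.60,0.77,,,,,,,35200,,,unknown,Sec 4.3.2
28R(NH2_OH_NH2),28R,A2B2C2,NH2_OH_NH2,,,,,,,,,0,,,Ci,Sec 4.3.2
26R(NH2_NO2_NH2),26R,A2B2C2,NH2_NO2_NH2,,,,,,,,,59400,,,unknown,Sec 4.3.2
28R(NH2_NO2_NH2),28R,A2B2C2,NH2_NO2_NH2,,,,,,,,,707,,,unknown,Sec 4.3.2
28R(NO2_NH2),28R,A3B3,NO2_NH2,,,,,,,,,10700,,,unknown,Sec 4.3.3
28M(NO2_NH2),28M,A3B3,NO2_NH2,,,,,,,,,19500,,,unknown,Sec 4.3.3
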