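table,variable,kind,n1,loc1,spread1,n2,loc2,spread2,weight,stat_name,stat,df,p,p_lt,d,ci_lo,ci_hi,sig_printed,dimorphic,masc_direction,note
table1,facial_area,median_iqr,40,28373,5580,40,26674,4903,NA,W,961,NA,0.12,FALSE,0.35,-0.09,0.79,FALSE,FALSE,NA,
table1,linear_alar_base_width,mean_sd,40,15.0,1.52,40,13.9,1.73,0.38,t,2.88,76.6,0.005,FALSE,0.64,0.19,1.10,TRUE,TRUE,1,
table1,linear_nose_height,mean_sd,40,38.7,3.28,40,37.9,4.00,1.54,t,0.96,75.1,0.34,FALSE,0.21,-0.23,0.66,FALSE,TRUE,1,
table1,linear_upper_lip_height,mean_sd,40,22.8,2.41,40,20.4,2.35,0.92,t,4.37,78.0,0.001,TRUE,0.98,0.51,1.45,TRUE,TRUE,1,
table1,geodesic_outer_canthal_width,mean_sd,40,100.6,8.07,40,94.6,7.11,0.39,t,3.52,76.8,0.0007,FALSE,0.79,0.33,1.25,TRUE,TRUE,1,
table1,geodesic_forehead_height,mean_sd,40,50.4,6.71,40,57.6,5.39,1.55,t,5.24,74.5,0.001,TRUE,1.17,0.69,1.65,TRUE,TRUE,-1,female-larger feature; masculinised shift is negative
table1,geodesic_forehead_width,mean_sd,40,147.6,9.38,40,141.6,12.1,0.52,t,2.51,73.5,0.01,FALSE,0.56,0.11,1.01,TRUE,TRUE,1,
table1,geodesic_right_upper_cheek_height,mean_sd,40,66.4,5.10,40,65.2,4.14,1.13,t,1.17,74.8,0.25,FALSE,0.26,-0.19,0.71,FALSE,FALSE,1,
table1,geodesic_nasal_tip_protrusion,median_iqr,40,14.8,2.35,40,14.3,2.72,1.31,W,954,NA,0.14,FALSE,0.38,-0.12,0.76,FALSE,FALSE,1,
table1,geodesic_nose_height,mean_sd,40,49.4,3.93,40,45.7,4.92,5.42,t,3.66,74.3,0.0005,FALSE,0.82,0.35,1.28,TRUE,TRUE,1,
table1,geodesic_upper_lip_height,mean_sd,40,25.5,3.33,40,22.4,3.34,0.54,t,4.05,78.0,0.0001,FALSE,0.90,0.44,1.37,TRUE,TRUE,1,
table1,geodesic_nasal_bridge_length,mean_sd,40,33.6,3.28,40,32.5,4.33,3.59,t,1.24,72.6,0.22,FALSE,0.28,-0.17,0.73,FALSE,FALSE,1,
table2,facial_area,mean_sd,30,27446,4331,69,26578,3720,NA,t,0.95,48.5,0.34,FALSE,0.22,-0.66,0.21,FALSE,NA,NA,printed CI inconsistent with printed d; stored verbatim
table2,masculinity_score,mean_sd,30,14.0,2.81,69,11.6,3.19,NA,t,3.89,62.3,0.0002,FALSE,0.81,0.36,1.26,TRUE,NA,NA,
table2,linear_alar_base_width,median_iqr,30,15.6,2.07,69,14.2,2.06,NA,W,570,NA,0.0004,FALSE,0.77,0.33,1.21,TRUE,NA,NA,
table2,linear_nose_height,mean_sd,30,38.0,3.60,69,36.9,4.68,NA,t,1.22,71.0,0.23,FALSE,0.24,-0.20,0.68,FALSE,NA,NA,
table2,linear_upper_lip_height,mean_sd,30,24.2,2.64,69,21.2,2.28,NA,t,5.32,48.8,0.001,TRUE,1.23,0.76,1.70,TRUE,NA,NA,
table2,geodesic_outer_canthal_width,mean_sd,30,100.7,7.19,69,95.0,8.03,NA,t,3.50,61.3,0.0009,FALSE,0.73,0.29,1.18,TRUE,NA,NA,
table2,geodesic_forehead_height,mean_sd,30,51.6,9.03,69,57.0,8.59,NA,t,2.82,52.8,0.007,FALSE,0.63,0.19,1.07,TRUE,NA,NA,
table2,geodesic_forehead_width,mean_sd,30,147.9,10.9,69,142.7,12.1,NA,t,2.10,61.1,0.04,FALSE,0.44,0.002,0.88,TRUE,NA,NA,
table2,geodesic_nose_height,mean_sd,30,49.3,4.68,69,43.9,5.78,NA,t,4.83,67.6,0.001,TRUE,0.97,0.52,1.43,TRUE,NA,NA,
table2,geodesic_upper_lip_height,mean_sd,30,26.7,3.21,69,23.5,3.28,NA,t,4.41,56.3,0.001,TRUE,0.96,0.50,1.41,TRUE,NA,NA,
table3,facial_area,mean_sd,25,26865,4053,60,26029,3273,NA,t,0.91,37.7,0.36,FALSE,0.24,-0.24,0.71,FALSE,NA,NA,
table3,masculinity_score,median_iqr,25,5.17,3.27,60,3.67,2.63,NA,W,459,NA,0.005,FALSE,0.63,0.15,1.10,TRUE,NA,NA,
table3,linear_alar_base_width,mean_sd,25,14.0,1.75,60,12.7,1.57,NA,t,3.30,40.8,0.002,FALSE,0.82,0.33,1.31,TRUE,NA,NA,
table3,linear_nose_height,mean_sd,25,37.6,3.56,60,35.6,3.85,NA,t,2.24,48.4,0.03,FALSE,0.54,0.04,1.00,TRUE,NA,NA,
table3,linear_upper_lip_height,median_iqr,25,21.6,2.17,60,21.0,2.21,NA,W,560,NA,0.07,FALSE,0.41,-0.06,0.88,FALSE,NA,NA,
table3,geodesic_outer_canthal_width,mean_sd,25,95.4,6.59,60,93.6,7.59,NA,t,1.12,51.5,0.27,FALSE,0.25,-0.72,0.22,FALSE,NA,NA,printed CI inconsistent with printed d; stored verbatim
table3,geodesic_forehead_height,mean_sd,25,53.8,7.86,60,55.8,6.57,NA,t,1.10,38.7,0.28,FALSE,0.28,-0.19,0.76,FALSE,NA,NA,
table3,geodesic_forehead_width,mean_sd,25,143.5,9.01,60,137.2,9.81,NA,t,2.86,48.7,0.006,FALSE,0.66,0.17,1.14,TRUE,NA,NA,
table3,geodesic_nose_height,mean_sd,25,45.2,3.82,60,44.1,4.66,NA,t,1.14,54.5,0.26,FALSE,-0.25,-0.73,0.22,FALSE,NA,NA,presumed sign typo in printed d (sibling mean exceeds control mean)
table3,geodesic_upper_lip_height,median_iqr,25,25.1,4.40,60,22.8,2.47,NA,W,351,NA,0.0001,FALSE,0.93,0.44,1.41,TRUE,NA,NA,
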