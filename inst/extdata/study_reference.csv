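section,measure,condition,mean,sd
context,summer_mean_temp_c,S,17.8,4.8
context,winter_mean_temp_c,W,-9.6,7.4
context,seasonal_temp_difference_c,NA,27.4,NA
context,mean_leg_length_m,NA,0.91,NA
context,gravity_m_s2,NA,9.806,NA
context,mean_velocity_scale_m_s,NA,2.98,NA
context,stance_time_var_decrease_printed_pct,NA,26.7,NA
context,fw_mos_change_w1_w2_printed_pct,NA,23.5,NA
stability,fw_mos_mean,S,-0.1349,0.0418
stability,fw_mos_mean,W1,-0.1706,0.0479
stability,fw_mos_mean,W2,-0.13,0.0389
stability,fw_mos_variability,S,0.0478,0.0094
stability,fw_mos_variability,W1,0.0458,0.0084
stability,fw_mos_variability,W2,0.0314,0.0071
stability,bw_mos_mean,S,0.8484,0.0683
stability,bw_mos_mean,W1,0.8852,0.0722
stability,bw_mos_mean,W2,0.8018,0.0552
stability,bw_mos_variability,S,0.0687,0.0112
stability,bw_mos_variability,W1,0.0733,0.0116
stability,bw_mos_variability,W2,0.0561,0.0144
stability,ml_mos_mean,S,0.0428,0.021
stability,ml_mos_mean,W1,0.0275,0.0218
stability,ml_mos_mean,W2,0.0321,0.0223
stability,ml_mos_variability,S,0.0218,0.0057
stability,ml_mos_variability,W1,0.0239,0.0037
stability,ml_mos_variability,W2,0.0255,0.005
stability,ap_lde,Summer,2.0249,0.1633
stability,ap_lde,Winter,2.0488,0.1601
stability,ml_lde,Summer,1.8651,0.1036
stability,ml_lde,Winter,1.9229,0.1157
stability,vt_lde,Summer,1.7788,0.0847
stability,vt_lde,Winter,1.8184,0.0897
stability,ap_regression_r2,Summer,0.9277,0.029
stability,ap_regression_r2,Winter,0.9025,0.0648
stability,ml_regression_r2,Summer,0.6495,0.1089
stability,ml_regression_r2,Winter,0.6017,0.0921
stability,ml_recovery_r2,Summer,0.1463,0.1089
stability,ml_recovery_r2,Winter,0.1275,0.0796
spatiotemporal,stride_time,S,3.5145,0.2254
spatiotemporal,stride_time,W1,3.4045,0.2352
spatiotemporal,stride_time,W2,3.4186,0.2329
spatiotemporal,stride_time_variability,S,0.0802,0.0169
spatiotemporal,stride_time_variability,W1,0.0809,0.0219
spatiotemporal,stride_time_variability,W2,0.0861,0.0308
spatiotemporal,stance_time,S,2.1198,0.1546
spatiotemporal,stance_time,W1,2.0161,0.1665
spatiotemporal,stance_time,W2,2.0988,0.1621
spatiotemporal,stance_time_variability,S,0.0987,0.0214
spatiotemporal,stance_time_variability,W1,0.0907,0.025
spatiotemporal,stance_time_variability,W2,0.0693,0.024
spatiotemporal,speed,S,0.5128,0.041
spatiotemporal,speed,W1,0.5283,0.0346
spatiotemporal,speed,W2,0.5086,0.0355
spatiotemporal,speed_variability,S,0.0214,0.0041
spatiotemporal,speed_variability,W1,0.0228,0.005
spatiotemporal,speed_variability,W2,0.0219,0.0071
spatiotemporal,stride_length,S,1.7711,0.0945
spatiotemporal,stride_length,W1,1.7677,0.0787
spatiotemporal,stride_length,W2,1.7106,0.0823
spatiotemporal,stride_length_variability,S,0.0601,0.01
spatiotemporal,stride_length_variability,W1,0.0673,0.0252
spatiotemporal,stride_length_variability,W2,0.0702,0.0254
spatiotemporal,step_width,S,0.0988,0.0457
spatiotemporal,step_width,W1,0.0832,0.0514
spatiotemporal,step_width,W2,0.0932,0.0533
spatiotemporal,step_width_variability,S,0.0346,0.0037
spatiotemporal,step_width_variability,W1,0.0364,0.0066
spatiotemporal,step_width_variability,W2,0.0373,0.0074
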