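setting_deg,model,session,phase,stat,rmse_x_deg,rmse_y_deg,rmse_rho_deg
0,mfnn,1,calibration,mean,0.391,0.386,0.551
0,mfnn,1,calibration,sd,0.037,0.063,0.062
0,mfnn,1,calibration,rsd_pct,9.4,16.3,11.2
0,mfnn,1,test,mean,0.344,0.499,0.611
0,mfnn,1,test,sd,0.068,0.061,0.058
0,mfnn,1,test,rsd_pct,19.8,12.2,9.5
0,mfnn,2,calibration,mean,0.377,0.453,0.592
0,mfnn,2,calibration,sd,0.038,0.053,0.025
0,mfnn,2,calibration,rsd_pct,10.1,11.6,4.2
0,mfnn,2,test,mean,0.416,0.476,0.634
0,mfnn,2,test,sd,0.046,0.041,0.044
0,mfnn,2,test,rsd_pct,10.9,8.7,6.9
0,mfnn,all,calibration,mean,0.384,0.419,0.572
0,mfnn,all,calibration,sd,0.038,0.067,0.051
0,mfnn,all,calibration,rsd_pct,9.9,16,9
0,mfnn,all,test,mean,0.38,0.488,0.622
0,mfnn,all,test,sd,0.068,0.053,0.053
0,mfnn,all,test,rsd_pct,18,10.9,8.5
30,mfnn,1,calibration,mean,0.362,0.388,0.532
30,mfnn,1,calibration,sd,0.075,0.046,0.076
30,mfnn,1,calibration,rsd_pct,20.7,11.8,14.4
30,mfnn,1,test,mean,0.389,0.446,0.594
30,mfnn,1,test,sd,0.064,0.073,0.081
30,mfnn,1,test,rsd_pct,16.3,16.3,13.6
30,mfnn,2,calibration,mean,0.352,0.387,0.526
30,mfnn,2,calibration,sd,0.067,0.049,0.067
30,mfnn,2,calibration,rsd_pct,19.2,12.7,12.8
30,mfnn,2,test,mean,0.427,0.397,0.586
30,mfnn,2,test,sd,0.069,0.034,0.049
30,mfnn,2,test,rsd_pct,16.2,8.4,8.3
30,mfnn,all,calibration,mean,0.357,0.388,0.529
30,mfnn,all,calibration,sd,0.071,0.048,0.072
30,mfnn,all,calibration,rsd_pct,20,12.3,13.6
30,mfnn,all,test,mean,0.408,0.422,0.59
30,mfnn,all,test,sd,0.069,0.062,0.067
30,mfnn,all,test,rsd_pct,17,14.6,11.3
60,mfnn,1,calibration,mean,0.413,0.391,0.573
60,mfnn,1,calibration,sd,0.103,0.052,0.092
60,mfnn,1,calibration,rsd_pct,24.9,13.3,16
60,mfnn,1,test,mean,0.425,0.425,0.608
60,mfnn,1,test,sd,0.084,0.093,0.088
60,mfnn,1,test,rsd_pct,19.8,22,14.4
60,mfnn,2,calibration,mean,0.37,0.35,0.512
60,mfnn,2,calibration,sd,0.051,0.062,0.065
60,mfnn,2,calibration,rsd_pct,13.8,17.7,12.6
60,mfnn,2,test,mean,0.4,0.427,0.589
60,mfnn,2,test,sd,0.086,0.055,0.078
60,mfnn,2,test,rsd_pct,21.5,12.9,13.3
60,mfnn,all,calibration,mean,0.392,0.371,0.542
60,mfnn,all,calibration,sd,0.084,0.061,0.085
60,mfnn,all,calibration,rsd_pct,21.5,16.4,15.7
60,mfnn,all,test,mean,0.413,0.426,0.598
60,mfnn,all,test,sd,0.086,0.077,0.084
60,mfnn,all,test,rsd_pct,20.8,18,14
60,linear,1,calibration,mean,0.482,0.458,0.668
60,linear,1,calibration,sd,0.106,0.08,0.118
60,linear,1,calibration,rsd_pct,22,17.5,17.6
60,linear,1,test,mean,0.519,0.482,0.712
60,linear,1,test,sd,0.061,0.137,0.128
60,linear,1,test,rsd_pct,11.7,28.5,18
60,linear,2,calibration,mean,0.42,0.453,0.619
60,linear,2,calibration,sd,0.06,0.108,0.117
60,linear,2,calibration,rsd_pct,14.3,23.7,18.9
60,linear,2,test,mean,0.443,0.49,0.662
60,linear,2,test,sd,0.054,0.098,0.103
60,linear,2,test,rsd_pct,12.3,20,15.5
60,linear,all,calibration,mean,0.451,0.456,0.643
60,linear,all,calibration,sd,0.092,0.095,0.12
60,linear,all,calibration,rsd_pct,20.3,20.8,18.6
60,linear,all,test,mean,0.481,0.486,0.687
60,linear,all,test,sd,0.069,0.119,0.119
60,linear,all,test,rsd_pct,14.4,24.5,17.3
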