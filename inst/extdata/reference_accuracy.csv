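setting_deg,model,session,user,phase,rmse_x_deg,rmse_y_deg,rmse_rho_deg
0,mfnn,1,1,calibration,0.378,0.303,0.485
0,mfnn,1,2,calibration,0.336,0.299,0.449
0,mfnn,1,3,calibration,0.361,0.458,0.583
0,mfnn,1,4,calibration,0.415,0.434,0.601
0,mfnn,1,5,calibration,0.414,0.392,0.570
0,mfnn,1,6,calibration,0.444,0.428,0.617
0,mfnn,1,1,test,0.298,0.526,0.605
0,mfnn,1,2,test,0.308,0.414,0.516
0,mfnn,1,3,test,0.359,0.498,0.614
0,mfnn,1,4,test,0.284,0.612,0.675
0,mfnn,1,5,test,0.330,0.466,0.571
0,mfnn,1,6,test,0.487,0.480,0.684
0,mfnn,2,1,calibration,0.305,0.512,0.596
0,mfnn,2,2,calibration,0.387,0.460,0.601
0,mfnn,2,3,calibration,0.365,0.494,0.615
0,mfnn,2,4,calibration,0.409,0.351,0.539
0,mfnn,2,5,calibration,0.425,0.429,0.604
0,mfnn,2,6,calibration,0.372,0.470,0.600
0,mfnn,2,1,test,0.443,0.516,0.680
0,mfnn,2,2,test,0.421,0.420,0.595
0,mfnn,2,3,test,0.336,0.462,0.571
0,mfnn,2,4,test,0.426,0.436,0.610
0,mfnn,2,5,test,0.482,0.486,0.685
0,mfnn,2,6,test,0.389,0.536,0.662
30,mfnn,1,1,calibration,0.308,0.322,0.446
30,mfnn,1,2,calibration,0.262,0.329,0.421
30,mfnn,1,3,calibration,0.366,0.424,0.561
30,mfnn,1,4,calibration,0.317,0.432,0.536
30,mfnn,1,5,calibration,0.469,0.424,0.632
30,mfnn,1,6,calibration,0.449,0.395,0.598
30,mfnn,1,1,test,0.333,0.407,0.526
30,mfnn,1,2,test,0.355,0.316,0.475
30,mfnn,1,3,test,0.359,0.480,0.600
30,mfnn,1,4,test,0.355,0.454,0.576
30,mfnn,1,5,test,0.409,0.553,0.687
30,mfnn,1,6,test,0.521,0.468,0.701
30,mfnn,2,1,calibration,0.249,0.383,0.457
30,mfnn,2,2,calibration,0.328,0.357,0.485
30,mfnn,2,3,calibration,0.383,0.450,0.591
30,mfnn,2,4,calibration,0.306,0.313,0.438
30,mfnn,2,5,calibration,0.383,0.450,0.591
30,mfnn,2,6,calibration,0.462,0.371,0.592
30,mfnn,2,1,test,0.381,0.362,0.526
30,mfnn,2,2,test,0.419,0.369,0.558
30,mfnn,2,3,test,0.361,0.436,0.566
30,mfnn,2,4,test,0.526,0.361,0.638
30,mfnn,2,5,test,0.361,0.436,0.566
30,mfnn,2,6,test,0.517,0.419,0.666
60,mfnn,1,1,calibration,0.305,0.328,0.448
60,mfnn,1,2,calibration,0.426,0.382,0.573
60,mfnn,1,3,calibration,0.279,0.367,0.461
60,mfnn,1,4,calibration,0.386,0.479,0.615
60,mfnn,1,5,calibration,0.546,0.352,0.649
60,mfnn,1,6,calibration,0.537,0.440,0.694
60,mfnn,1,1,test,0.433,0.259,0.505
60,mfnn,1,2,test,0.513,0.495,0.713
60,mfnn,1,3,test,0.347,0.350,0.493
60,mfnn,1,4,test,0.281,0.511,0.583
60,mfnn,1,5,test,0.487,0.429,0.649
60,mfnn,1,6,test,0.488,0.506,0.703
60,mfnn,2,1,calibration,0.336,0.307,0.455
60,mfnn,2,2,calibration,0.348,0.291,0.453
60,mfnn,2,3,calibration,0.298,0.406,0.504
60,mfnn,2,4,calibration,0.367,0.286,0.465
60,mfnn,2,5,calibration,0.440,0.358,0.567
60,mfnn,2,6,calibration,0.433,0.452,0.626
60,mfnn,2,1,test,0.434,0.342,0.552
60,mfnn,2,2,test,0.304,0.388,0.493
60,mfnn,2,3,test,0.289,0.475,0.556
60,mfnn,2,4,test,0.374,0.397,0.546
60,mfnn,2,5,test,0.476,0.474,0.672
60,mfnn,2,6,test,0.524,0.490,0.717
60,linear,1,1,calibration,0.351,0.334,0.485
60,linear,1,2,calibration,0.620,0.455,0.769
60,linear,1,3,calibration,0.352,0.416,0.545
60,linear,1,4,calibration,0.472,0.584,0.751
60,linear,1,5,calibration,0.497,0.434,0.659
60,linear,1,6,calibration,0.600,0.529,0.800
60,linear,1,1,test,0.433,0.279,0.515
60,linear,1,2,test,0.564,0.609,0.830
60,linear,1,3,test,0.520,0.325,0.614
60,linear,1,4,test,0.576,0.621,0.847
60,linear,1,5,test,0.441,0.469,0.644
60,linear,1,6,test,0.578,0.590,0.826
60,linear,2,1,calibration,0.378,0.373,0.531
60,linear,2,2,calibration,0.502,0.640,0.814
60,linear,2,3,calibration,0.377,0.445,0.583
60,linear,2,4,calibration,0.334,0.307,0.454
60,linear,2,5,calibration,0.458,0.423,0.624
60,linear,2,6,calibration,0.468,0.529,0.707
60,linear,2,1,test,0.425,0.460,0.626
60,linear,2,2,test,0.472,0.646,0.800
60,linear,2,3,test,0.435,0.429,0.611
60,linear,2,4,test,0.337,0.371,0.501
60,linear,2,5,test,0.482,0.438,0.652
60,linear,2,6,test,0.504,0.598,0.783
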