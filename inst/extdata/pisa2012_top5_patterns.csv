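country,rank,pattern,proportion
United Arab Emirates,1,"(0,0,0,0)",0.363
United Arab Emirates,2,"(1,0,0,0)",0.112
United Arab Emirates,3,"(1,0,0,1)",0.112
United Arab Emirates,4,"(1,1,1,1)",0.100
United Arab Emirates,5,"(0,0,1,0)",0.007
Argentina,1,"(0,0,0,0)",0.494
Argentina,2,"(1,0,0,0)",0.240
Argentina,3,"(1,0,0,1)",0.060
Argentina,4,"(1,0,1,1)",0.059
Argentina,5,"(1,1,1,1)",0.053
Bulgaria,1,"(0,0,0,0)",0.234
Bulgaria,2,"(1,0,0,1)",0.212
Bulgaria,3,"(0,0,0,1)",0.166
Bulgaria,4,"(1,1,1,1)",0.130
Bulgaria,5,"(1,0,0,0)",0.103
Chile,1,"(0,0,0,0)",0.389
Chile,2,"(1,0,1,1)",0.222
Chile,3,"(1,0,0,0)",0.155
Chile,4,"(1,1,1,1)",0.113
Chile,5,"(1,0,0,1)",0.065
Colombia,1,"(0,0,0,0)",0.479
Colombia,2,"(1,0,0,1)",0.178
Colombia,3,"(1,0,0,0)",0.138
Colombia,4,"(1,1,1,1)",0.051
Colombia,5,"(0,0,0,1)",0.037
Costa Rica,1,"(0,0,0,0)",0.645
Costa Rica,2,"(1,0,0,1)",0.151
Costa Rica,3,"(0,0,0,1)",0.061
Costa Rica,4,"(0,1,1,0)",0.034
Costa Rica,5,"(1,0,0,0)",0.025
Jordan,1,"(0,0,0,0)",0.511
Jordan,2,"(1,0,0,0)",0.196
Jordan,3,"(1,1,0,1)",0.051
Jordan,4,"(0,0,1,0)",0.051
Jordan,5,"(1,1,1,1)",0.051
Kazakhstan,1,"(0,0,0,0)",0.332
Kazakhstan,2,"(1,0,0,0)",0.248
Kazakhstan,3,"(1,1,1,1)",0.118
Kazakhstan,4,"(1,0,1,1)",0.070
Kazakhstan,5,"(1,0,1,0)",0.033
Mexico,1,"(0,0,0,0)",0.415
Mexico,2,"(1,0,0,1)",0.159
Mexico,3,"(1,0,0,0)",0.129
Mexico,4,"(1,1,1,1)",0.114
Mexico,5,"(1,0,1,1)",0.085
Peru,1,"(0,0,0,0)",0.603
Peru,2,"(1,0,0,1)",0.112
Peru,3,"(1,0,1,0)",0.056
Peru,4,"(1,1,1,1)",0.045
Peru,5,"(0,0,0,1)",0.040
Romania,1,"(0,0,0,0)",0.510
Romania,2,"(0,1,1,1)",0.143
Romania,3,"(1,0,0,1)",0.132
Romania,4,"(0,0,1,0)",0.080
Romania,5,"(1,0,0,0)",0.048
Serbia,1,"(0,0,0,0)",0.422
Serbia,2,"(1,0,1,1)",0.112
Serbia,3,"(1,0,0,1)",0.108
Serbia,4,"(1,0,0,0)",0.075
Serbia,5,"(0,0,0,1)",0.073
Tunisia,1,"(0,0,0,0)",0.490
Tunisia,2,"(1,0,0,0)",0.202
Tunisia,3,"(1,1,1,1)",0.090
Tunisia,4,"(1,0,0,1)",0.059
Tunisia,5,"(0,0,0,1)",0.049
Uruguay,1,"(0,0,0,0)",0.459
Uruguay,2,"(1,0,0,0)",0.189
Uruguay,3,"(1,0,0,1)",0.122
Uruguay,4,"(1,0,1,1)",0.097
Uruguay,5,"(1,1,1,1)",0.049
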