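group,n,variable,overlap,mean_range,overlap_over_mean
Brocchinioideae-Lindmanioideae,25,AI,403.49,5911.66,0.068
Hechtioideae,26,AI,106.34,5026.96,0.021
Navioideae,28,AI,826.78,4710.64,0.176
Pitcairnia-Fosterella,208,AI,509.97,10187.66,0.050
Xeric Clade,79,AI,554.83,3955.18,0.140
Puyoideae,99,AI,499.21,7549.20,0.066
C3 early-diverging Bromelioideae,22,AI,87.88,12449.85,0.007
CAM early-diverging Bromelioideae,77,AI,252.93,5551.77,0.046
Brocchinioideae-Lindmanioideae,25,P_seas,1.960,21.86,0.090
Hechtioideae,26,P_seas,1.800,18.40,0.098
Navioideae,28,P_seas,1.260,16.65,0.076
Pitcairnia-Fosterella,208,P_seas,4.210,32.94,0.128
Xeric Clade,79,P_seas,6.321,23.33,0.271
Puyoideae,99,P_seas,3.594,31.10,0.116
C3 early-diverging Bromelioideae,22,P_seas,1.083,36.54,0.030
CAM early-diverging Bromelioideae,77,P_seas,2.320,29.13,0.080
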