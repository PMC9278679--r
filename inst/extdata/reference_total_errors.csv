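study,component,setup,te_published
phantom,tx_mm,C1,2.74
phantom,tx_mm,C2,0.59
phantom,ty_mm,C1,0.69
phantom,ty_mm,C2,1.52
phantom,tz_mm,C1,1.17
phantom,tz_mm,C2,0.84
phantom,pitch_deg,C1,1.10
phantom,pitch_deg,C2,0.33
phantom,roll_deg,C1,0.66
phantom,roll_deg,C2,0.08
phantom,yaw_deg,C1,1.68
phantom,yaw_deg,C2,0.04
patient,tx_mm,C1,1.81
patient,tx_mm,C2,1.39
patient,ty_mm,C1,4.03
patient,ty_mm,C2,0.96
patient,tz_mm,C1,1.88
patient,tz_mm,C2,0.81
patient,pitch_deg,C1,0.14
patient,pitch_deg,C2,0.27
patient,roll_deg,C1,0.42
patient,roll_deg,C2,0.12
patient,yaw_deg,C1,0.09
patient,yaw_deg,C2,0.10
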