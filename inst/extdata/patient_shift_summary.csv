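component,setup,min,max,mean,median,iqr
tx_mm,C1,-3.60,11.20,1.75,1.20,2.30
tx_mm,C2,-4.80,1.50,-1.31,-1.50,3.20
ty_mm,C1,-4.70,8.60,4.00,3.70,2.80
ty_mm,C2,-3.50,1.40,-0.83,-0.70,1.40
tz_mm,C1,-7.30,7.20,-1.87,-2.40,6.30
tz_mm,C2,-10.60,8.50,0.79,1.80,3.55
pitch_deg,C1,-1.03,1.03,-0.13,-0.23,0.66
pitch_deg,C2,-0.69,0.97,0.27,0.29,0.66
roll_deg,C1,-0.74,1.37,0.42,0.57,0.66
roll_deg,C2,-1.50,1.83,0.11,0.06,0.43
yaw_deg,C1,-0.69,0.69,0.08,0.11,0.86
yaw_deg,C2,-1.03,1.26,0.09,0.11,0.52
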