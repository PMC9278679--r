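component,setup,min,max,mean,median,iqr
tx_mm,C1,-3.60,-1.20,-2.70,-2.90,0.60
tx_mm,C2,-1.50,2.00,0.34,0.50,1.50
ty_mm,C1,-0.70,0.30,-0.50,-0.50,0.20
ty_mm,C2,0.90,1.90,1.44,1.45,0.30
tz_mm,C1,-2.20,2.50,1.15,0.90,2.80
tz_mm,C2,-0.90,2.10,0.82,1.40,1.40
pitch_deg,C1,0.11,2.01,1.10,1.12,0.59
pitch_deg,C2,-1.55,0.69,-0.33,-0.29,0.63
roll_deg,C1,0.17,0.92,0.66,0.74,0.29
roll_deg,C2,-0.86,1.26,0.07,-0.14,0.56
yaw_deg,C1,0.46,2.29,1.68,1.86,0.30
yaw_deg,C2,-0.52,1.09,-0.01,-0.29,0.65
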