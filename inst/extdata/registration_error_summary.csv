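group,mean,sd
xy,-0.48,0.35
z,-0.19,0.04
rotations,0.04,0.1
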