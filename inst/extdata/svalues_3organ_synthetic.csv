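source,target,gy_per_bq_s
A,A,2.0e-13
A,B,1.0e-15
A,C,2.0e-15
B,A,1.5e-15
B,B,3.0e-13
B,C,5.0e-16
C,A,2.5e-15
C,B,1.0e-15
C,C,5.0e-13
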