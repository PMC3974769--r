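name	start	end
TM2	0	21
EC1	21	36
TM3	36	62
IC2	62	76
TM4	76	100
EC2	100	126
TM5	126	150
IC3	150	166
TM6	166	190
EC3	190	196
TM7	196	215
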