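subject	s1	s2	s3
S1	100	100	100
S2	100	100	100
S3	100	100	100
S4	94.44	100	100
S5	100	100	100
S6	100	100	100
S7	100	94.44	94.44
S8	100	100	100
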