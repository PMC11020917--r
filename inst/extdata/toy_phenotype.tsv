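sample_id	phenotype
s1	0
s2	0
s3	0
s4	0
s5	0
s6	0
s7	1
s8	1
s9	1
s10	1
s11	1
s12	1
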