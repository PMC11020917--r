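sample_id	n1	n2	n3	n4	n5
s1	47	16	111	27	73
s2	40	40	62	52	87
s3	68	35	39	22	57
s4	60	32	58	70	154
s5	42	70	23	30	26
s6	71	14	26	52	45
s7	15	89	58	40	53
s8	77	162	57	51	82
s9	68	118	25	35	69
s10	102	101	64	35	129
s11	23	76	44	34	20
s12	40	99	41	14	55
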