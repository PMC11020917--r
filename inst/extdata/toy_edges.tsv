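from	to
n1	n2
n2	n3
n3	n4
n4	n5
n5	n1
n2	n5
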