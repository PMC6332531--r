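# toy network: A and B interact and share partners P1, P2, P3
A	B
A	P1
A	P2
A	P3
B	P1
B	P2
B	P3
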