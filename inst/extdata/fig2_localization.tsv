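# P1 and P3 co-localize with both A and B; P2 shares a compartment with
# each of A and B separately but the three have no common location
A	nucleus
A	cytoplasm
B	nucleus
B	membrane
P1	nucleus
P2	cytoplasm
P2	membrane
P3	nucleus
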