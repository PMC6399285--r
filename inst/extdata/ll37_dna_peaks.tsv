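# sample: LL37-dsDNA isoelectric complex, 2D square columnar lattice
# q_unit: inverse_angstrom
q	h	k
0.182	1	0
0.258	1	1
0.419	1	2
0.529	2	2
0.680	2	3
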