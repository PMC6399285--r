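# sample: melittin-dsDNA isoelectric complex, tetragonal columnar lattice
# q_unit: inverse_angstrom
q	h	k	l
0.173	1	0	0
0.215	0	0	1
0.244	1	1	0
0.308	1	1	1
0.345	2	0	0
0.386	2	1	0
0.429	2	1	1
0.454	1	1	2
0.492	2	2	0
0.518	3	0	0
0.577	0	0	3
0.622	3	2	0
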