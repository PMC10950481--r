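#name=GAGA anchor_offset=0 cutoff=5.72
pos	1	2	3	4	5
A	0.020000	0.940000	0.020000	0.940000	0.020000
C	0.020000	0.020000	0.020000	0.020000	0.020000
G	0.940000	0.020000	0.940000	0.020000	0.940000
T	0.020000	0.020000	0.020000	0.020000	0.020000
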