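#name=DPE anchor_offset=0 cutoff=3.064
pos	1	2	3	4	5
A	0.480000	0.020000	0.480000	0.020000	0.326666
C	0.020000	0.020000	0.020000	0.480000	0.326667
G	0.480000	0.940000	0.020000	0.020000	0.326667
T	0.020000	0.020000	0.480000	0.480000	0.020000
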