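#name=BBCA+1BW anchor_offset=3 cutoff=3.543
pos	1	2	3	4	5	6
A	0.020000	0.020000	0.020000	0.940000	0.020000	0.480000
C	0.326666	0.326666	0.940000	0.020000	0.326666	0.020000
G	0.326667	0.326667	0.020000	0.020000	0.326667	0.020000
T	0.326667	0.326667	0.020000	0.020000	0.326667	0.480000
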