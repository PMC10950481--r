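#name=Inr anchor_offset=2 cutoff=3.959
pos	1	2	3	4	5	6	7
A	0.020000	0.020000	0.940000	0.250000	0.480000	0.020000	0.020000
C	0.480000	0.480000	0.020000	0.250000	0.020000	0.480000	0.480000
G	0.020000	0.020000	0.020000	0.250000	0.020000	0.020000	0.020000
T	0.480000	0.480000	0.020000	0.250000	0.480000	0.480000	0.480000
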