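aa	hydropathy	volume
A	1.8	88.6
R	-4.5	173.4
N	-3.5	114.1
D	-3.5	111.1
C	2.5	108.5
Q	-3.5	143.8
E	-3.5	138.4
G	-0.4	60.1
H	-3.2	153.2
I	4.5	166.7
L	3.8	166.7
K	-3.9	168.6
M	1.9	162.9
F	2.8	189.9
P	-1.6	112.7
S	-0.8	89.0
T	-0.7	116.1
W	-0.9	227.8
Y	-1.3	193.6
V	4.2	140.0
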