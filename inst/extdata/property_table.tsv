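aa	hydrophobicity	volume	polarity	charge	hbond	flexibility	helix_prop	sheet_prop
A	1.8	88.6	8.1	0	0	0.984	1.42	0.83
C	2.5	108.5	5.5	0	1	0.906	0.70	1.19
D	-3.5	111.1	13.0	-1	4	1.068	1.01	0.54
E	-3.5	138.4	12.3	-1	4	1.094	1.51	0.37
F	2.8	189.9	5.2	0	0	0.915	1.13	1.38
G	-0.4	60.1	9.0	0	0	1.031	0.57	0.75
H	-3.2	153.2	10.4	0	3	0.950	1.00	0.87
I	4.5	166.7	5.2	0	0	0.927	1.08	1.60
K	-3.9	168.6	11.3	1	2	1.102	1.16	0.74
L	3.8	166.7	4.9	0	0	0.935	1.21	1.30
M	1.9	162.9	5.7	0	1	0.952	1.45	1.05
N	-3.5	114.1	11.6	0	4	1.048	0.67	0.89
P	-1.6	112.7	8.0	0	0	1.049	0.57	0.55
Q	-3.5	143.8	10.5	0	4	1.037	1.11	1.10
R	-4.5	173.4	10.5	1	5	1.008	0.98	0.93
S	-0.8	89.0	9.2	0	2	1.046	0.77	0.75
T	-0.7	116.1	8.6	0	2	0.997	0.83	1.19
V	4.2	140.0	5.9	0	0	0.931	1.06	1.70
W	-0.9	227.8	5.4	0	1	0.904	1.08	1.37
Y	-1.3	193.6	6.2	0	2	0.929	0.69	1.47
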