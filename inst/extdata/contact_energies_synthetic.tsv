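type	Y	F	R	K	G	S	T	Q	N	X
Y	-17.00	-15.50	-10.50	1.95	-1.20	-1.20	-1.20	-1.60	-1.60	-1.20
F	-15.50	-14.00	-10.00	1.50	-1.00	-1.00	-1.00	-1.40	-1.40	-1.00
R	-10.50	-10.00	-2.00	2.00	-0.80	-0.80	-0.80	-1.00	-1.00	-0.80
K	1.95	1.50	2.00	1.00	-0.20	-0.20	-0.20	-0.30	-0.30	-0.20
G	-1.20	-1.00	-0.80	-0.20	-0.80	-0.80	-0.80	-0.90	-0.90	-0.80
S	-1.20	-1.00	-0.80	-0.20	-0.80	-0.80	-0.80	-0.90	-0.90	-0.80
T	-1.20	-1.00	-0.80	-0.20	-0.80	-0.80	-0.80	-0.90	-0.90	-0.80
Q	-1.60	-1.40	-1.00	-0.30	-0.90	-0.90	-0.90	-1.00	-1.00	-0.90
N	-1.60	-1.40	-1.00	-0.30	-0.90	-0.90	-0.90	-1.00	-1.00	-0.90
X	-1.20	-1.00	-0.80	-0.20	-0.80	-0.80	-0.80	-0.90	-0.90	-0.90
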