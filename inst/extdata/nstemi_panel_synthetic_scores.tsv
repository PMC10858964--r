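gene	score	fold
FAM46C	11.9	0.38
HBQ1	11.3	0.35
CA1	10.9	0.55
KRT1	10.4	0.33
XK	10.0	0.47
BTNL3	9.7	0.30
FEXH	9.4	0.28
GLRX5	9.2	0.26
ACOX2	9.0	0.44
ZBTB32	8.8	0.24
IPO11	8.6	0.62
LDLR	8.5	0.22
NT5DC2	8.3	0.20
CD244	8.1	0.18
TNNT2	7.6	0.14
CRP	7.2	0.12
CHI3L1	6.8	0.10
MYBPC3	6.4	0.09
FKBP5	6.0	0.08
CST3	5.6	0.07
MPO	5.2	0.06
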