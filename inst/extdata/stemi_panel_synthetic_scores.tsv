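gene	score	fold
DUSP1	18.2	0.71
PADI4	17.5	0.66
CDA	16.9	0.62
VNN3	16.1	0.58
CYP4F3	15.6	0.55
MMP9	15.0	0.52
NOV	14.4	0.49
ARG1	13.9	0.46
IRS2	13.5	0.44
DUSP2	13.1	0.41
CRISPLD2	12.8	0.38
HMGB2	12.5	0.35
TNFRS12A	12.2	0.33
TNNT2	11.4	0.21
CRP	10.8	0.18
LGALS3	9.7	0.15
CHI3L1	9.1	0.12
MME	8.6	0.10
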