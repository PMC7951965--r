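hexamer	score
GGAGGA	0.41
GAGGAT	0.53
AGGATT	0
GGATTG	0.24
GATTGC	0.12
ATTGCT	-0.11
GCTTGA	0
CTTGAG	0
TTGAGG	-0.33
TGAGGC	0
GAGGCC	0.38
AGGCCA	0
GTTCAA	0.22
TTCAAG	0.26
TCAAGA	0.46
CAAGAC	0.71
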