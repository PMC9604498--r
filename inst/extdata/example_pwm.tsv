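A	0.25	0.04	0.02	0.03	0.26	0.24
C	0.27	0.03	0.02	0.03	0.25	0.27
G	0.23	0.90	0.94	0.91	0.22	0.24
T	0.25	0.03	0.02	0.03	0.27	0.25
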