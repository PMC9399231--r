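>KLF_like
A	0.02	0.02	0.02	0.02	0.02	0.02	0.02	0.02	0.02	0.02
C	0.02	0.02	0.02	0.02	0.94	0.02	0.02	0.02	0.02	0.94
G	0.94	0.94	0.94	0.94	0.02	0.94	0.94	0.94	0.94	0.02
T	0.02	0.02	0.02	0.02	0.02	0.02	0.02	0.02	0.02	0.02
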