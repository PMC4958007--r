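background_id	mutation_key
F416	3846gA
F421	3861gA
F178	3132tA
J15	2441aC
J20	2456aC
G72	4154cA
H57	4669gA
A44	131aC
C8	1562cA
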