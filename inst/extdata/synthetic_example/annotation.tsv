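feature_id	class	start	end	frame_offset
geneA	gene	1	1536	0
geneB	gene	999	1361	0
geneC	gene	1540	1800	0
geneD	gene	1940	2395	0
geneE	gene	2155	2430	0
geneJ	gene	2398	2520	0
geneF	gene	2600	3880	0
geneG	gene	3940	4470	0
geneH	gene	4500	5480	0
D-promoter	promoter	1909	1935	0
J-terminator	terminator	2525	2560	0
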