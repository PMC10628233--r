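ko_id	S001	S002	S003
K00001	0.4	0.3	0.5
K00001|g__Faecalibacterium.s__Faecalibacterium_prausnitzii	0.3	0.2	0.4
K00001|unclassified	0.1	0.1	0.1
K01476	0.6	0.7	0.5
K01476|g__Bacteroides.s__Bacteroides_uniformis	0.6	0.7	0.5
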