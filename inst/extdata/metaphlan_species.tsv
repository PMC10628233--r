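clade_name	S001	S002	S003
k__Bacteria	100.0	100.0	100.0
k__Bacteria|p__Firmicutes	60.0	55.0	70.0
k__Bacteria|p__Firmicutes|g__Faecalibacterium	40.0	30.0	50.0
k__Bacteria|p__Firmicutes|g__Faecalibacterium|s__Faecalibacterium_prausnitzii	40.0	30.0	50.0
k__Bacteria|p__Firmicutes|g__Roseburia|s__Roseburia_intestinalis	20.0	25.0	20.0
k__Bacteria|p__Bacteroidetes|g__Bacteroides|s__Bacteroides_uniformis	40.0	45.0	30.0
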