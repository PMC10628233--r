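pathway	ko_id
map00220	K01476
map00220	K00928
map00270	K01611
map00270	K00928
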