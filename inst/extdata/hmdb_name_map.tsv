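name	hmdb_id
L-Tryptophan	HMDB0000929
L-Arginine	HMDB0000517
Urea	HMDB0000294
L-Ornithine	HMDB0000123
L-Methionine	HMDB0000696
L-Aspartate	HMDB0000191
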