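ko_id	reaction_id	substrates	products	equation_text
K01476	R00551	HMDB0000517	HMDB0000294;HMDB0000123	L-Arginine + H2O <=> L-Ornithine + Urea
K01611	R08359	HMDB0000696	HMDB0001414	S-Adenosyl-L-methioninamine <=> decarboxylated product
K00928	R00480	HMDB0000191	HMDB0062186	L-Aspartate + ATP <=> 4-phospho-L-aspartate + ADP
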