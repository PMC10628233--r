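sample_id	cohort	status	age	gender	bmi	antibiotic_use	timepoint_index
S001	cohortA	IBD	34	female	22.1	FALSE	1
S002	cohortA	healthy	41	male	24.3	FALSE	1
S003	cohortB	CD	29	female	21.0	FALSE	1
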