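key	value
associations_reported	260
known_panelapp	241
novel_candidates	19
moi_consistent	237
known_subgroup_level	43
comparator_known	249
comparator_novel	579
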