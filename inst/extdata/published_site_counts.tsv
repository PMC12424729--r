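quantity	numerator	denominator
mtf2_overlap_at_nucleation	1057	1109
jarid2_overlap_at_nucleation	880	1109
eed_cage_mutant_overlap	908	1109
deg_after_reintroduction	1967	48440
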