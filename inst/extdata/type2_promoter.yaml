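# Default type-2 Pol III internal promoter model.
# Boxes are IUPAC consensus strings matched with a mismatch budget; replace
# a box with per-base probability rows (A/C/G/T) to use a PWM instead.
a_box: TRGCNNARYNNG
b_box: GTTCRANNC
spacer_range: [20, 40]
max_mismatches: 2
min_score: 80%
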