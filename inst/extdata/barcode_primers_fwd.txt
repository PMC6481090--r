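# Row (forward) barcoding primers: GAT spacer + 8 bp barcode + m13fwd-derived linker
iR5_A	GATTATAGCCTGTAAAACGACGGCCAGT
iR5_B	GATATAGAGGCGTAAAACGACGGCCAGT
iR5_C	GATCCTATCCTGTAAAACGACGGCCAGT
iR5_D	GATGGCTCTGAGTAAAACGACGGCCAGT
iR5_E	GATAGGCGAAGGTAAAACGACGGCCAGT
iR5_F	GATTAATCTTAGTAAAACGACGGCCAGT
iR5_G	GATCAGGACGTGTAAAACGACGGCCAGT
iR5_H	GATGTACTGACGTAAAACGACGGCCAGT
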