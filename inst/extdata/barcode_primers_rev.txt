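# Column (reverse) barcoding primers: GAT spacer + 8 bp barcode + m13rev-derived linker
iC701	GATATTACTCGAGCGGATAACAATTTCACACAGGA
iC702	GATTCCGGAGAAGCGGATAACAATTTCACACAGGA
iC703	GATCGCTCATTAGCGGATAACAATTTCACACAGGA
iC704	GATGAGATTCCAGCGGATAACAATTTCACACAGGA
iC705	GATATTCAGAAAGCGGATAACAATTTCACACAGGA
iC706	GATGAATTCGTAGCGGATAACAATTTCACACAGGA
iC707	GATCTGAAGCTAGCGGATAACAATTTCACACAGGA
iC708	GATTAATGCGCAGCGGATAACAATTTCACACAGGA
iC709	GATCGGCTATGAGCGGATAACAATTTCACACAGGA
iC710	GATTCCGCGAAAGCGGATAACAATTTCACACAGGA
iC711	GATTCTCGCGCAGCGGATAACAATTTCACACAGGA
iC712	GATAGCGATAGAGCGGATAACAATTTCACACAGGA
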