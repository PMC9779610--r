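name	sequence	orientation	target_region	intronic_tail_len
IGHV1-FW	CCTCCTCAACTGTGCCCGCC	forward	V	0
IGHV3-FW	GCGCAAAATTTGTTACGGGC	forward	V	0
IGHV4-FW	GCCGTGTTCAAGACGGGGTT	forward	V	0
IGHV5-FW	CGTGGGTATACAACCCTATA	forward	V	0
IGH-J-A-1	GGACTCACGAGGAGACGGTG	reverse	J	8
IGH-J-A-2	ACTCACGAGGAGACGGTGAC	reverse	J	6
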