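# Orthogonal strand-displacement gate sets for sequential dSTORM.
# Sequences 5'->3'. IDT-style modification tokens are stored as metadata;
# lower-case bases are a non-hybridizing 3' linker (TT spacer before the
# azide used for antibody conjugation).
>A_protector
GCCTGCTTTATCTCTGTTCTACTATTTCCGtt/3AzideN/
>A_template
/5Alex647N/CGGAAATAGTAGAACAGAGATAAAGCAGGCAAACGAAA
>A_invader
TTTCGTTTGCCTGCTTTATCTCTGTTCTACTATTTCCG
>B_protector
GGGTCAAGTCAAAGTCAAGTATCAAGTCGGtt/3AzideN/
>B_template
/5Alex647N/CCGACTTGATACTTGACTTTGACTTGACCCTTGATATT
>B_invader
AATATCAAGGGTCAAGTCAAAGTCAAGTATCAAGTCGG
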