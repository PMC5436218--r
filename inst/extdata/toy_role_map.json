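{"ligands":{"Q1":{"head_beads":"Q1_H","tail_beads":"Q1_T1","species":"PLQ"}},"protein_reference":["R1","R2","R3","R4"]}
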