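dusp	inducers	substrates	predicted_inducers	provenance
DUSP1	ERK,p38	JNK	NA	known
DUSP2	ERK,JNK	ERK,p38	NA	known
DUSP3	NA	ERK,JNK,p38	JNK	predicted
DUSP4	ERK	ERK,JNK	NA	known
DUSP5	ERK	ERK	NA	known
DUSP9	NA	ERK	JNK	predicted
DUSP16	NA	JNK,p38	ERK	predicted
DUSP23	NA	ERK,JNK,p38	JNK	predicted
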