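# DUSP9 regulation model
# induction of DUSP9 is unknown; this file uses the model-predicted inducer (JNK)
#input: Herceptin Basal
#readout: Survival
HER2* = not Herceptin
ERK* = (HER2 or Basal) and not DUSP9
JNK* = HER2
p38* = HER2
DUSP9* = JNK
Survival* = ERK or not (JNK and p38)
Herceptin = True
Basal = True
HER2 = False
ERK = True
JNK = False
p38 = False
DUSP9 = True
Survival = True
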