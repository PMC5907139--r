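# DUSP1 regulation model
#input: Herceptin Basal
#readout: Survival
HER2* = not Herceptin
ERK* = HER2
JNK* = (HER2 or Basal) and not DUSP1
p38* = HER2
DUSP1* = ERK or p38
Survival* = ERK or not (JNK and p38)
Herceptin = True
Basal = True
HER2 = False
ERK = True
JNK = False
p38 = False
DUSP1 = True
Survival = True
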