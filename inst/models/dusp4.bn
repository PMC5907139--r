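# DUSP4 regulation model
#input: Herceptin Basal
#readout: Survival
HER2* = not Herceptin
ERK* = (HER2 or Basal) and not DUSP4
JNK* = (HER2 or Basal) and not DUSP4
p38* = HER2
DUSP4* = ERK
Survival* = ERK or not (JNK and p38)
Herceptin = True
Basal = True
HER2 = False
ERK = True
JNK = False
p38 = False
DUSP4 = True
Survival = True
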