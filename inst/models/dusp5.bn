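# DUSP5 regulation model
#input: Herceptin Basal
#readout: Survival
HER2* = not Herceptin
ERK* = (HER2 or Basal) and not DUSP5
JNK* = HER2
p38* = HER2
DUSP5* = ERK
Survival* = ERK or not (JNK and p38)
Herceptin = True
Basal = True
HER2 = False
ERK = True
JNK = False
p38 = False
DUSP5 = True
Survival = True
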