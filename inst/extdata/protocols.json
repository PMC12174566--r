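{
  "Reference": {"GB20": -3, "GV20": 3, "GV16": 3, "BL23": 3, "KI3": 3, "GB39": 3},
  "R1": {"KI8": -5, "SP1": -3, "HT9": -1, "SI18": 4, "BL62": 2, "GB19": 1, "CV2": -2},
  "R2": {"KI16": -5, "LU8": 2, "ST10": 1, "HT2": 5, "BL7": -1, "SP3": -5},
  "R3": {"GB14": 4, "PC7": 3, "TE22": -4, "GV28": -2, "CV6": -1},
  "R4": {"CV24": 5, "BL49": -5, "SI12": 3, "SP16": -3, "ST41": 1, "LI20": -1},
  "R5": {"EXHN4": 4, "EXB3": -4, "LU1": -2, "LR2": 2, "KI9": -3},
  "M1": {"LR1": -3, "LR14": 3, "SP2": 3, "SP19": -3, "KI10": -3, "KI21": 3},
  "M2": {"LR6": 3, "LR12": -3, "SP6": -3, "SP21": 3, "KI1": 3, "KI3": -3},
  "M3": {"LR10": -3, "LR11": 3, "SP10": 3, "SP16": -3, "KI15": -3, "KI19": 3},
  "M4": {"LR12": 3, "LR3": -5, "SP17": 4, "SP18": -2, "KI23": 3, "KI20": -4},
  "M5": {"LR2": 4, "LR14": -4, "SP4": -1, "SP5": 2, "KI17": -4, "KI27": 1},
  "C1": {"GB20": -3, "GB25": 3, "BL40": 3, "BL55": -3, "ST40": -3, "ST45": 3},
  "C2": {"GB1": 3, "GB10": -3, "BL15": -3, "BL25": 3, "ST38": 3, "ST39": -3},
  "C3": {"GB40": 3, "GB44": -3, "BL60": -3, "BL65": 3, "ST1": 3, "ST10": -3},
  "C4": {"GB1": 4, "GB26": -5, "BL36": 3, "BL21": -2, "ST2": 2, "ST10": -1},
  "C5": {"GB43": 5, "GB26": -4, "BL20": -5, "BL41": 3, "ST6": 4, "ST42": -4}
}
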