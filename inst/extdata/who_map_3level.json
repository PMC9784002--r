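{
 "High|High|High": "A",
 "High|High|Medium": "B",
 "High|High|Low": "B",
 "High|Medium|High": "E",
 "High|Medium|Medium": "F",
 "High|Medium|Low": "B",
 "High|Low|High": "E",
 "High|Low|Medium": "E",
 "High|Low|Low": "F",
 "Medium|High|High": "C",
 "Medium|High|Medium": "D",
 "Medium|High|Low": "B",
 "Medium|Medium|High": "G",
 "Medium|Medium|Medium": "A",
 "Medium|Medium|Low": "B",
 "Medium|Low|High": "G",
 "Medium|Low|Medium": "E",
 "Medium|Low|Low": "F",
 "Low|High|High": "C",
 "Low|High|Medium": "D",
 "Low|High|Low": "D",
 "Low|Medium|High": "G",
 "Low|Medium|Medium": "C",
 "Low|Medium|Low": "D",
 "Low|Low|High": "G",
 "Low|Low|Medium": "G",
 "Low|Low|Low": "H"
}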