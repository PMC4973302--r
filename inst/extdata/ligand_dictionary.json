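{
  "LUT": {
    "description": "Lutein (C40H56O2): beta,epsilon-carotene-3,3'-diol. Unprimed atoms form the beta-ionone half, primed atoms the epsilon-ionone half. Hydroxyls O3/O3' sit on ring carbons C3/C3'.",
    "heavy_atoms": ["C1","C2","C3","C4","C5","C6","C7","C8","C9","C10",
                    "C11","C12","C13","C14","C15","C16","C17","C18","C19","C20","O3",
                    "C1'","C2'","C3'","C4'","C5'","C6'","C7'","C8'","C9'","C10'",
                    "C11'","C12'","C13'","C14'","C15'","C16'","C17'","C18'","C19'","C20'","O3'"],
    "hydroxyl": ["O3", "O3'"],
    "rings": {
      "beta":    ["C1", "C2", "C3", "C4", "C5", "C6"],
      "epsilon": ["C1'", "C2'", "C3'", "C4'", "C5'", "C6'"]
    },
    "inversion": {
      "C1": "C1'", "C2": "C2'", "C3": "C3'", "C4": "C4'", "C5": "C5'",
      "C6": "C6'", "C7": "C7'", "C8": "C8'", "C9": "C9'", "C10": "C10'",
      "C11": "C11'", "C12": "C12'", "C13": "C13'", "C14": "C14'", "C15": "C15'",
      "C16": "C16'", "C17": "C17'", "C18": "C18'", "C19": "C19'", "C20": "C20'",
      "O3": "O3'"
    }
  }
}
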