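# IgG N-glycome panel: HILIC-UPLC chromatogram divided into 24 peaks
# (GP1-GP24). Trait groupings follow the conventional UPLC aggregation
# (Pucic-style structure assignments); they are editable defaults, not
# measured quantities.
name: uplc_24
platform: UPLC
peaks: [GP1, GP2, GP3, GP4, GP5, GP6, GP7, GP8, GP9, GP10, GP11, GP12, GP13, GP14, GP15, GP16, GP17, GP18, GP19, GP20, GP21, GP22, GP23, GP24]
# GP5 is oligomannose; GP16-GP24 are sialylated
galactosylation_excluded: [GP5, GP16, GP17, GP18, GP19, GP20, GP21, GP22, GP23, GP24]
traits:
  - trait: G0
    numerator: {GP1: 1, GP2: 1, GP3: 1, GP4: 1, GP6: 1}
    denominator: TOTAL
    scale: 1
  - trait: G1
    numerator: {GP7: 1, GP8: 1, GP9: 1, GP10: 1, GP11: 1, GP12: 1}
    denominator: TOTAL
    scale: 1
  - trait: G2
    numerator: {GP13: 1, GP14: 1, GP15: 1}
    denominator: TOTAL
    scale: 1
  - trait: S
    numerator: {GP16: 1, GP17: 1, GP18: 1, GP19: 1, GP20: 1, GP21: 1, GP22: 1, GP23: 1, GP24: 1}
    denominator: TOTAL
    scale: 1
  - trait: B
    numerator: {GP3: 1, GP6: 1, GP11: 1, GP12: 1, GP15: 1, GP19: 1, GP22: 1, GP24: 1}
    denominator: TOTAL
    scale: 1
  - trait: F
    numerator: {GP1: 1, GP4: 1, GP6: 1, GP9: 1, GP10: 1, GP11: 1, GP12: 1, GP14: 1, GP15: 1, GP16: 1, GP18: 1, GP19: 1, GP23: 1, GP24: 1}
    denominator: TOTAL
    scale: 1
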