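# IgG N-glycome panel: CGE-LIF electropherogram integrated into 27 peaks.
# Trait groupings follow the conventional CGE-LIF aggregation of structurally
# related peaks (galactosylation classes over the neutral peaks, sialylated
# peaks GP1-GP13, bisected and core-fucosylated structure sets). GP20 carries
# weight 2 in G1: the peak co-elutes two monogalactosylated structures.
name: cge_lif_27
platform: CGE-LIF
peaks: [GP1, GP2, GP3, GP4, GP5, GP6, GP7, GP8, GP9, GP10, GP11, GP12, GP13, GP14, GP15, GP16, GP17, GP18, GP19, GP20, GP21, GP22, GP23, GP24, GP25, GP26, GP27]
# sialylated peaks are not classified by galactosylation state
galactosylation_excluded: [GP1, GP2, GP3, GP4, GP5, GP6, GP7, GP8, GP9, GP10, GP11, GP12, GP13]
traits:
  - trait: G0
    numerator: {GP14: 1, GP15: 1, GP18: 1}
    denominator: TOTAL
    scale: 1
  - trait: G1
    numerator: {GP16: 1, GP17: 1, GP19: 1, GP20: 2, GP21: 1, GP22: 1, GP23: 1, GP24: 1}
    denominator: TOTAL
    scale: 1
  - trait: G2
    numerator: {GP25: 1, GP26: 1, GP27: 1}
    denominator: TOTAL
    scale: 1
  - trait: S
    numerator: {GP1: 1, GP2: 1, GP3: 1, GP4: 1, GP5: 1, GP6: 1, GP7: 1, GP8: 1, GP9: 1, GP10: 1, GP11: 1, GP12: 1, GP13: 1}
    denominator: TOTAL
    scale: 1
  - trait: B
    numerator: {GP2: 1, GP4: 1, GP11: 1, GP13: 1, GP14: 1, GP18: 1, GP19: 1, GP20: 1, GP23: 1, GP24: 1, GP25: 1, GP27: 1}
    denominator: TOTAL
    scale: 1
  - trait: F
    numerator: {GP3: 1, GP4: 1, GP7: 1, GP8: 1, GP12: 1, GP13: 1, GP15: 1, GP18: 1, GP21: 1, GP22: 1, GP23: 1, GP24: 1, GP26: 1, GP27: 1}
    denominator: TOTAL
    scale: 1
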