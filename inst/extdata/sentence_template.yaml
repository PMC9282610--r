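condition: sentence
nodes:
  S1: {layer: S, children: []}
  S2: {layer: S, children: []}
  S3: {layer: S, children: []}
  S4: {layer: S, children: []}
  PO1: {layer: PO, children: [S1]}
  PO2: {layer: PO, children: [S2]}
  PO3: {layer: PO, children: [S3]}
  PO4: {layer: PO, children: [S4]}
  RB1: {layer: RB, children: [PO1, PO2]}
  RB2: {layer: RB, children: [PO3, PO4]}
  P_DP: {layer: P, children: [RB1]}
  P_s: {layer: P, children: [P_DP, RB2]}
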