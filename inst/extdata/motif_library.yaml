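# Curated NBS-domain (NB-ARC) motif library: regex-style residue classes,
# one class per position. Consensus = first residue of each class. Widths
# 6-50; min_score defaults to 80% of width (rounded up).
motifs:
  - name: P-loop
    pattern: "G[MSE][GA]G[VIL]GK[TS]T"
  - name: RNBS-A
    pattern: "[FL][DN][LIV][VRK][AG]W[VAI][STC][VIL]S[QH]"
  - name: Kinase-2
    pattern: "[KR][KR][FY][LIV][LIV][LIVF]DD[VIL][WD]"
  - name: RNBS-B
    pattern: "[KR][ST][RK][LIV][LIV][VIT]TTR[ND]"
  - name: RNBS-C
    pattern: "[YF][ED][VIL][ED][LMV][LIV]S[ED][DN][ES]"
  - name: GLPL
    pattern: "GLPLA[LIV][KR][VT]"
  - name: RNBS-D
    pattern: "[CF][FL][LIV][YF][CG][SA][LIV]FP[KE]"
  - name: MHDL
    pattern: "MHD[LIV][VLM][RK]"
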