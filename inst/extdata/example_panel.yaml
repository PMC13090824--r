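# Example primer panel: classic barcode loci with degenerate bases.
# Toy sequences for demonstration; supply your own panels for real studies.
pairs:
  - name: 16S_bact
    forward: AGAGTTTGATCMTGGCTCAG
    reverse: TACGGYTACCTTGTTACGACTT
    min_length: 500
    max_length: 2000
  - name: CO1_metazoa
    forward: GGTCAACAAATCATAAAGATATTGG
    reverse: TAAACTTCAGGGTGACCAAAAAATCA
    max_length: 1000
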