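locus:
  flank5: ATGAAGGCCTTCGAGTCCCTCAAGTCCTTC
  flank3: CCGCCACCGCCGCCGCCGCCGCCGCCTCCTCAGCTTCCTCAGCC
  primer_fwd: ATGAAGGCCTTCGAGTCCC
  primer_rev: GGCTGAGGAAGCTGAGGA
alleles:
  - name: normal_16
    cag: 16
    structure: canonical
  - name: normal_17
    cag: 17
    structure: canonical
  - name: mutant_51
    cag: 51
    structure: canonical
guides:
  - name: gRNA1
    spacer: GCTGCTGCTGGAAGGACTTG
  - name: gRNA2
    spacer: CTGCTGCTGCTGCTGCTGGA
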