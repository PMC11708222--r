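panel_id: HO-5site
reference_fasta: ho5_synthetic_reference.fasta
numbering_offset: 0
sites:
- site_id: '189'
  codon: 189
  flank_nt: 6
  alleles:
  - A
  - T
  - S
- site_id: '223'
  codon: 223
  flank_nt: 6
  alleles:
  - G
  - D
  - S
- site_id: '405'
  codon: 405
  flank_nt: 6
  alleles:
  - L
  - S
- site_id: '475'
  codon: 475
  flank_nt: 6
  alleles:
  - L
  - H
deletion:
  start_codon: 524
  end_codon: 559
  repeat_len_nt: 8
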