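name: gpcv2-crispr
version: v2
promoter:
  name: CAGp
  sequence: AAGAATCCTCCGAACCTTTAGACTCTCCGGCTACCGTACCTAGTTATTTCAGAAAACGGTACAGTTCGCTAAAGGCCACC
leader: ATG
gpcs:
- index: 1
  recombinase:
    name: Cre
    ligand: GIB
    nls: yes
    split_halves:
    - TGGGAGTCAACTCGGACCTGTCTGCCGTACTCCATGCAAAAAGAACTAGACCCAATATCT
    - GAAAGCCTTAAGCAAATATGTTACTCAAAACCATCGGGACTTGGACTATCGCTACGCTCC
    sites:
      name: loxP
      left_site: ATAACTTCGTATAATGTATGCTATACGAAGTTAT
      right_site: ATAACTTCGTATAATGTATGCTATACGAAGTTAT
      scar_site: ATAACTTCGTATAATGTATGCTATACGAAGTTAT
      symmetric: yes
  payloads:
  - name: sgAPC
    kind: sgRNA
    sequence: CGTTCATGCGGGATTTGGGT
    tags:
    - Csy4_20nt_core
    - MALAT1_triple_helix
    locus: APC
  terminator: TGCGGGTGGCACAGTACGTATCGTTATGGCTTTACCAGCGCTCCTAGAACCTCTCTGGGCGGAGTCTCTTACGCGTGATTCAGCCGCACAGAGGGCAAACAGAACACAGCCAGTTTAGCA
- index: 2
  recombinase:
    name: Flp
    ligand: ABA
    nls: yes
    split_halves:
    - TTTCAAAAGGCTGATCACCCCCGTACTGTTGATATATACCCATTATACAGGGGCGCATAT
    - GCCTGTCGCGCTCGAAGACCCGTTGGCTTGACTTTAAGAGAGTCATTCCTTGAATCAGAC
    sites:
      name: FRT
      left_site: GAAGTTCCTATTCTCTAGAAAGTATAGGAACTTC
      right_site: GAAGTTCCTATTCTCTAGAAAGTATAGGAACTTC
      scar_site: GAAGTTCCTATTCTCTAGAAAGTATAGGAACTTC
      symmetric: yes
  payloads:
  - name: sgMLH1
    kind: sgRNA
    sequence: TTAATCCCCTTTTCGTAGTA
    tags:
    - Csy4_20nt_core
    - MALAT1_triple_helix
    locus: MLH1
  terminator: TGCGGGTGGCACAGTACGTATCGTTATGGCTTTACCAGCGCTCCTAGAACCTCTCTGGGCGGAGTCTCTTACGCGTGATTCAGCCGCACAGAGGGCAAACAGAACACAGCCAGTTTAGCA
- index: 3
  recombinase:
    name: PhiC31
    ligand: GIB
    nls: yes
    split_halves:
    - CCGTTCTATAGGACTTCGAAGCACACGAAGACCGACCCCGGTACCCGCTCGAGTCTACCG
    - ATCCCACGTTCGAGCTGCTATTACCCCCACGGAACCGGCTCGATGCCCACTAATCTCACA
    sites:
      name: att
      left_site: TGGTGGCCCGATCGAGCGAAGAGAACGGGATCGGTGCTGGTCTGCCGTTG
      right_site: GACAACGGACTTCAGGTCAAGCTACGATGTCGCAAGGCGTGATAGACTATGGAC
      scar_site: TGGTGGCCCGATCGAGCGAAGAGAATGTCGCAAGGCGTGATAGACTATGGAC
      symmetric: no
  payloads:
  - name: sgSMAD4
    kind: sgRNA
    sequence: GTAACGGATTTCTACCCGTA
    tags:
    - Csy4_20nt_core
    - MALAT1_triple_helix
    locus: SMAD4
  terminator: TGCGGGTGGCACAGTACGTATCGTTATGGCTTTACCAGCGCTCCTAGAACCTCTCTGGGCGGAGTCTCTTACGCGTGATTCAGCCGCACAGAGGGCAAACAGAACACAGCCAGTTTAGCA
terminal_payloads:
- name: sgTP53
  kind: sgRNA
  sequence: CTGAATCTAGGGACTACATG
  tags:
  - Csy4_20nt_core
  - MALAT1_triple_helix
  locus: TP53
att_wrapper: ~
itr_flanks: no
frame_pad: yes
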