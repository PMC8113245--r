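name: gpcv2-crispra
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
  - name: sgRHOXF2
    kind: sgRNA
    sequence: GACTACAAATTCGATCGTTC
    tags:
    - Csy4_20nt_core
    - MALAT1_triple_helix
    locus: RHOXF2
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
  - name: sgASCL1
    kind: sgRNA
    sequence: CGCGAGCTCATAGCCGTCCC
    tags:
    - Csy4_20nt_core
    - MALAT1_triple_helix
    locus: ASCL1
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
  - name: sgHBG1
    kind: sgRNA
    sequence: TCAATTTCAACCCGAGGGGA
    tags:
    - Csy4_20nt_core
    - MALAT1_triple_helix
    locus: HBG1
  terminator: TGCGGGTGGCACAGTACGTATCGTTATGGCTTTACCAGCGCTCCTAGAACCTCTCTGGGCGGAGTCTCTTACGCGTGATTCAGCCGCACAGAGGGCAAACAGAACACAGCCAGTTTAGCA
terminal_payloads:
- name: sgTTN
  kind: sgRNA
  sequence: TGGCCAATGCGCAGGTATCT
  tags:
  - Csy4_20nt_core
  - MALAT1_triple_helix
  locus: TTN
att_wrapper: ~
itr_flanks: no
frame_pad: yes
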