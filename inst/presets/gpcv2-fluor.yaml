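name: gpcv2-fluor
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
  - name: BFP
    kind: protein
    sequence: TGGCCGGACGGCGCGTGTACGTACAGTCGCCCGTTCCGCTGCAGGTTTATATACCTCTCG
    tags:
    - PEST
    - P2A
    locus: ~
  - name: Zeo
    kind: protein
    sequence: CGAAGGGGGAGAGGCCAGTCCCGACCTGGAGGGCCGAAACCCTCTGAGACAACAGGCCGC
    tags:
    - PEST
    - P2A
    - Zeo
    locus: ~
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
  - name: GFP
    kind: protein
    sequence: ATCTGGTCACGCTCGGAATACCACTATTTACTGTCCCATCCGGTATTCTTGCCGTTCTCA
    tags:
    - PEST
    - P2A
    locus: ~
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
  - name: mCherry
    kind: protein
    sequence: CACTGTCGCATTTTGGGTTCTGACGGAATATCGTCAAGTCTCTCGGTCGTATCTCTAACG
    tags:
    - PEST
    - P2A
    locus: ~
  terminator: TGCGGGTGGCACAGTACGTATCGTTATGGCTTTACCAGCGCTCCTAGAACCTCTCTGGGCGGAGTCTCTTACGCGTGATTCAGCCGCACAGAGGGCAAACAGAACACAGCCAGTTTAGCA
terminal_payloads:
- name: iRFP720
  kind: protein
  sequence: CGTCTATCAGACATAGGATCAGCATGTTCGGAAGGCTATATGACTTTTTATGCGTATATT
  tags:
  - PEST
  - P2A
  locus: ~
att_wrapper: ~
itr_flanks: no
frame_pad: yes
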