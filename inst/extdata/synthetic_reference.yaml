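name: synthetic-bcrabl1-p210
comment: 'Fully synthetic stand-in for the BCR-ABL1 p210 fusion-transcript amplicon:
  random open reading frame with clinically numbered codon anchors and the published
  primer pair embedded at the product ends. Not a human sequence.'
breakpoint: e14a2
frame_offset: 0
fwd_primer: TGACCAACTCGTGTGTGAAACTC
rev_primer: TCCACTTCGTCTGAGATACTGGATT
codon_anchors:
- gene: BCR
  exon: BCR-e12
  offset: 21
  codon: 360
- gene: ABL1
  exon: ABL1-a2
  offset: 0
  codon: 235
exons:
- gene: BCR
  name: BCR-e12
  ordinal: 12
  sequence: TCTCTTAACAGGCATAGGTATGACCAACTCGTGTGTGAAACTCTAAATGACGAGGCGCAATCGCTTAGTTTGATGCTATCAGTTGTCCAATCGGGGCTCTCCAGCCGACCGGCGATTTGGGTACGAAAGCGGTCAAGGTCG
- gene: BCR
  name: BCR-e13
  ordinal: 13
  sequence: CAACCTCGTATACTGATCGCTTGTCCAGAGGTAAATAACCTCTATATCAGGGGAGGGATTTGCACTGTGCATGGTCAGGACTTACAATCCCGGAAATTAGCTGGC
- gene: BCR
  name: BCR-e14
  ordinal: 14
  sequence: CAAAGGAATGCTGAAAGAGGACCAAGATCTCACCGATCGGCCTGTCCGTGTTGCTGTAGGTTGCGATATTATGCT
- gene: ABL1
  name: ABL1-a2
  ordinal: 2
  sequence: AGTCCGTCGCGAATTCAGACCATTCCAGTATCGGCCTGGGTTTATCTAAGTTTTTACCGTGAAGGCGAGCGTGCGGTTGCCCAGGCCAAATGGAGGGTTCTAAGTGGCAAGAGGGTCAGACACGATCTCGGCGTTCACAGCCGAATGCGCTTGTGTGACCAAACTCATACCGAT
- gene: ABL1
  name: ABL1-a3
  ordinal: 3
  sequence: CCTCATGTCGGAGGAGAGGGAATGGCTACTGCAACGTGCGGTAAAAAAGTGCGGTCGCCTCATTTCACTAATCCATGCCTTAAGAAAAGAGCGCTTGGCGTCAGTCTCGGACATAGGTCATCGTTTAACAAACACACAGCCAATAAAGGGCTTCTGCATACGACAAGGTCAGGC
- gene: ABL1
  name: ABL1-a4
  ordinal: 4
  sequence: CCCTACAAGGACAAGAACGCACTCTTCCTTGGGATGTTGATTTGGATTCGCAAATTGCCATTAATTTTACGTGGCCAGTTCATGCACGTCGCAACACAGGGACAATTAGCTATACATGCATTTAGCATACCACGACACGGCACACACCTTGTCCTCTTTCCAGGCATCTGCATC
- gene: ABL1
  name: ABL1-a5
  ordinal: 5
  sequence: CTACTAGCAGGGTTGCCCGAGCCTCATTGCAAAAGTACGCCTAGAGTAGGTAGGTATCTTCACGTAGTCTGGCTGTATGAATGGTTCCGCGCCCGCTTAATGTATCTGACGCGATTGCCTGGATCTGACCATTGGGCAGGCATCTCTAAAACCCCGTGGTCCCTAGCCCCCCAA
- gene: ABL1
  name: ABL1-a6
  ordinal: 6
  sequence: GATACGAATCCGCAGAAACTGGGACTCGCCGAATCGCCAGTTGTTACGCAAGGGCCGTTGCATGAAAGGCCCAAATCGTATTTAAGGCGGTCGCCTCGTTTTACACGTAAGTTGAATCTCCCGCGGATCTTCACGCGGGCTCGTCTACCGGTGGTTTTTGCTCTCTTGAAGCAC
- gene: ABL1
  name: ABL1-a7
  ordinal: 7
  sequence: TACAACCGCAGTGAAACTATGATTCTACTAATAAATATACGCGTACTGACGCCTGACAACCAAGATGAAAATTGGTACGCAGAGAACAGGAACCTAACCTTCCTTAATGGTTCCCTTTCTCGCCACCACGTGTGCGAATTCTTAAGGTTAGGCCGACGGAGATGCTTTATGAGA
- gene: ABL1
  name: ABL1-a8
  ordinal: 8
  sequence: GGGCACCTTTTTCTCATTTGCAGGTTTTACGTATACATGTGTGGGATAAGAAGCTATGTTCCGATTCAGCTGGTCATCCTGGATCG
- gene: ABL1
  name: ABL1-a9
  ordinal: 9
  sequence: ATGGTTCCAGATTTACATGTGTGGGATCAGGTCTCTACACTTACGTGAGGGAATCACTGATGGTTCTACAGTGGGAAGCGGCGAGACAGTGATGGACCGTTTGTTGTTGAGTGATGAGATTAAATCCAGTATCTCAGACGAAGTGGACGGGGCAAAGCTTTT
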