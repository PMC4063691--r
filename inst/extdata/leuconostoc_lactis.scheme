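# Eight-locus MLST scheme for Leuconostoc lactis.
# Loci in alphabetical order; this order defines profile columns.
# reference_span: coordinates on the L. mesenteroides subsp. mesenteroides
# ATCC 8293 genome, documentation only.
name: leuconostoc_lactis
locus: carB
  forward_primer: ATGGGTTGTGGGAGTTGTA
  reverse_primer: ACTTGTTGCGTCGTGGTGT
  amplicon_length: 833
  reference_span: 1202174-1205353
locus: groEL
  forward_primer: CGGTGATAAGGCTGCTGT
  reverse_primer: TTTGTTGGGTCCACGATA
  amplicon_length: 892
  reference_span: 1734716-1736335
locus: murC
  forward_primer: TTTCATAGGCGAACTCAT
  reverse_primer: GTGCCATTGTTTGGTCAG
  amplicon_length: 619
  reference_span: 679802-681136
locus: pheS
  forward_primer: TTTCTTAGGTTTAGGCTTTG
  reverse_primer: CCTTTCGGTTAAATTGTGA
  amplicon_length: 665
  reference_span: 406737-407813
locus: pyrG
  forward_primer: AGCAAACACCCAAGAACG
  reverse_primer: TGGTGAAGCGAAGACAAA
  amplicon_length: 598
  reference_span: 481322-482935
locus: recA
  forward_primer: GGAGTCGTTTCTGGGTTAC
  reverse_primer: GTTGCTTTAGGCGTTGGTG
  amplicon_length: 550
  reference_span: 555064-556221
locus: rpoB
  forward_primer: CACTGTGCGGTCGTCTTCC
  reverse_primer: GCGTTCTCCTGGTATCTATT
  amplicon_length: 608
  reference_span: 1798123-1801731
locus: uvrC
  forward_primer: AGAAATACAAGCCGTACTACAA
  reverse_primer: TCTTCATCAGCGGAACCAA
  amplicon_length: 560
  reference_span: 483053-484852
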