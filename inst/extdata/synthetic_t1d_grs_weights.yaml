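snps:
- rsid: rs689
  effect_allele: A
  other_allele: T
  weight: 0.69
  eaf: 0.7
- rsid: rs2304256
  effect_allele: C
  other_allele: A
  weight: 0.33
  eaf: 0.72
- rsid: rs11594656
  effect_allele: T
  other_allele: A
  weight: 0.17
  eaf: 0.7
- rsid: rs1265564
  effect_allele: C
  other_allele: A
  weight: 0.16
  eaf: 0.58
- rsid: rs2292239
  effect_allele: T
  other_allele: C
  weight: 0.3
  eaf: 0.34
- rsid: rs3087243
  effect_allele: G
  other_allele: A
  weight: 0.18
  eaf: 0.55
- rsid: rs12722495
  effect_allele: T
  other_allele: C
  weight: 0.48
  eaf: 0.09
haplotype:
  snp_a: rs2187668
  snp_b: rs3957146
  effect_alleles:
  - A
  - A
  weights:
  - - 0.0
    - 1.27
    - 2.34
  - - 1.03
    - 3.87
    - 2.34
  - - 2.04
    - 1.03
    - 0.0
reference_percentiles: ~
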