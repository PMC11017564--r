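# Default genotype rule table for gamma-PGA gene-cluster architectures,
# version bacillus-pga-v1.
#
# Genotypes G1-G7 are defined by gene content (required/forbidden) plus, for
# G3, the pgdS-ywtC spacing; subtypes are defined by gene order and strand
# pattern along the genome. Genotype rules are evaluated in file order with
# first-match-wins (G3 precedes G2 because they share gene content and only
# the spacing separates them); then the subtypes of the winning genotype are
# evaluated in file order. Strand patterns are written in genome order over
# {+,-,*} (* = wildcard). Spacing windows are +/-10% around observed values;
# published spacings are strain observations, not sharp thresholds.
#
# Where only partial order/strand information is available for a subtype,
# the pattern is completed deterministically (distinct permutations and
# strand flips) so that every packaged subtype is discriminable; see the
# methods vignette.
version: bacillus-pga-v1
rules:
- label: G1
  kind: genotype
  required: [pghB, pghC, pghL, pghZ, ggt, racE, pgsB, pgsC, pgsA, ywtC, pgdS]
  forbidden: []
- label: SG1.1
  kind: subtype
  parent: G1
  order: [pghB, pghC, pghL, pghZ, ggt, racE, pgsB, pgsC, pgsA, ywtC, pgdS]
  strands: "++++++-----"
- label: SG1.2
  kind: subtype
  parent: G1
  order: [pghB, pghC, pghL, pghZ, ggt, racE, pgsB, pgsC, pgsA, ywtC, pgdS]
  strands: "+++-++-----"
- label: SG1.3
  kind: subtype
  parent: G1
  order: [pghB, pghC, pghL, pghZ, racE, ggt, pgsB, pgsC, pgsA, ywtC, pgdS]
  strands: "++++++-----"
- label: SG1.4
  kind: subtype
  parent: G1
  order: [ggt, pghB, pghC, pghL, pghZ, racE, pgsB, pgsC, pgsA, ywtC, pgdS]
  strands: "++++++-----"
- label: SG1.5
  kind: subtype
  parent: G1
  order: [pghB, pghC, pghL, pghZ, racE, ggt, pgsB, pgsC, pgsA, ywtC, pgdS]
  strands: "+++-++-----"
- label: SG1.6
  kind: subtype
  parent: G1
  order: [pghB, pghC, pghL, pghZ, racE, ggt, pgsB, pgsC, pgsA, ywtC, pgdS]
  strands: "++++-+----+"
- label: SG1.7
  kind: subtype
  parent: G1
  order: [pghB, pghC, pghL, pghZ, ggt, racE, pgsB, pgsC, pgsA, ywtC, pgdS]
  strands: "+++-+------"
- label: SG1.8
  kind: subtype
  parent: G1
  order: [ggt, pghB, pghC, pghL, pghZ, racE, pgsB, pgsC, pgsA, ywtC, pgdS]
  strands: "++++-------"
- label: SG1.9
  kind: subtype
  parent: G1
  order: [pghZ, pghB, pghC, pghL, ggt, racE, pgsB, pgsC, pgsA, ywtC, pgdS]
  strands: "-++++------"
- label: G3
  kind: genotype
  required: [pghB, pghC, pghL, ggt, racE, pgsB, pgsC, pgsA, ywtC, pgdS]
  forbidden: [pghZ]
  spacing:
  - {a: pgdS, b: ywtC, min: 1548, max: 1000000000}
- label: SG3.1
  kind: subtype
  parent: G3
  spacing:
  - {a: pgdS, b: ywtC, min: 1548, max: 1892}
- label: SG3.2
  kind: subtype
  parent: G3
  spacing:
  - {a: pgdS, b: ywtC, min: 1893, max: 10000}
- label: SG3.3
  kind: subtype
  parent: G3
  spacing:
  - {a: pgdS, b: ywtC, min: 10001, max: 52429}
- label: SG3.4
  kind: subtype
  parent: G3
  spacing:
  - {a: pgdS, b: ywtC, min: 52430, max: 64082}
- label: G2
  kind: genotype
  required: [pghB, pghC, pghL, ggt, racE, pgsB, pgsC, pgsA, ywtC, pgdS]
  forbidden: [pghZ]
- label: SG2.1
  kind: subtype
  parent: G2
  order: [pghB, pghC, pghL, ggt, racE, pgsB, pgsC, pgsA, ywtC, pgdS]
  strands: "++++------"
- label: SG2.2
  kind: subtype
  parent: G2
  order: [ggt, pghB, pghC, pghL, racE, pgsB, pgsC, pgsA, ywtC, pgdS]
  strands: "++++------"
- label: SG2.3
  kind: subtype
  parent: G2
  order: [pghB, pghC, pghL, ggt, racE, pgsB, pgsC, pgsA, ywtC, pgdS]
  strands: "++++++++++"
- label: SG2.4
  kind: subtype
  parent: G2
  order: [pghB, pghC, pghL, racE, ggt, pgsB, pgsC, pgsA, ywtC, pgdS]
  strands: "+++-+-----"
- label: SG2.5
  kind: subtype
  parent: G2
  order: [ggt, pghB, pghC, pghL, racE, pgsB, pgsC, pgsA, ywtC, pgdS]
  strands: "++++++++++"
- label: SG2.6
  kind: subtype
  parent: G2
  order: [racE, pghB, pghC, pghL, ggt, pgsB, pgsC, pgsA, ywtC, pgdS]
  strands: "-++++-----"
- label: SG2.7
  kind: subtype
  parent: G2
  order: [pgsB, pgsC, pgsA, ywtC, pgdS, racE, ggt, pghB, pghC, pghL]
  strands: "------++++"
- label: SG2.8
  kind: subtype
  parent: G2
  order: [pghB, pghC, pghL, racE, ggt, pgsB, pgsC, pgsA, ywtC, pgdS]
  strands: "++++++++++"
- label: G4
  kind: genotype
  required: [pghC, pghL, ggt, racE, pgsB, pgsC, pgsA, ywtC, pgdS]
  forbidden: [pghB, pghZ]
- label: G5
  kind: genotype
  required: [pghB, racE, pgsB, pgsC, pgsA, ywtC, pgdS]
  forbidden: [pghC, pghL, pghZ, ggt]
- label: G6
  kind: genotype
  required: [pghB, pghC, ggt, racE, pgsB, pgsC, pgsA, ywtC, pgdS]
  forbidden: [pghL, pghZ]
- label: SG6.1
  kind: subtype
  parent: G6
  order: [pghB, pghC, ggt, racE, pgsB, pgsC, pgsA, ywtC, pgdS]
  strands: "+++------"
- label: SG6.2
  kind: subtype
  parent: G6
  order: [ggt, pghB, pghC, racE, pgsB, pgsC, pgsA, ywtC, pgdS]
  strands: "+++------"
- label: SG6.3
  kind: subtype
  parent: G6
  order: [pghB, pghC, racE, ggt, pgsB, pgsC, pgsA, ywtC, pgdS]
  strands: "++-+-----"
- label: SG6.4
  kind: subtype
  parent: G6
  order: [racE, pghB, pghC, ggt, pgsB, pgsC, pgsA, ywtC, pgdS]
  strands: "-+++-----"
- label: SG6.5
  kind: subtype
  parent: G6
  order: [pgsB, pgsC, pgsA, ywtC, pgdS, racE, ggt, pghB, pghC]
  strands: "------+++"
- label: SG6.6
  kind: subtype
  parent: G6
  order: [pghB, pghC, ggt, racE, pgsB, pgsC, pgsA, ywtC, pgdS]
  strands: "+++++++++"
- label: SG6.7
  kind: subtype
  parent: G6
  order: [ggt, pghB, pghC, racE, pgsB, pgsC, pgsA, ywtC, pgdS]
  strands: "+++++++++"
- label: SG6.8
  kind: subtype
  parent: G6
  order: [pghB, pghC, ggt, racE, pgsB, pgsC, pgsA, ywtC, pgdS]
  strands: "++-------"
- label: SG6.9
  kind: subtype
  parent: G6
  order: [ggt, pghB, pghC, racE, pgsB, pgsC, pgsA, ywtC, pgdS]
  strands: "-++------"
- label: SG6.10
  kind: subtype
  parent: G6
  order: [racE, pghB, pghC, ggt, pgsB, pgsC, pgsA, ywtC, pgdS]
  strands: "-++------"
- label: G7
  kind: genotype
  required: [pghB, pghC, ggt, racE, pgsB, pgsC, pgsA, pgdS]
  forbidden: [ywtC, pghL, pghZ]
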