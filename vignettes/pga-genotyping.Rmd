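---
title: "Genotyping gamma-PGA gene clusters in Bacillus genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping gamma-PGA gene clusters in Bacillus genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgatyper)
```

## The biological problem

Poly-gamma-glutamate (gamma-PGA) is an extracellular polymer of D- and
L-glutamate produced chiefly by *Bacillus* species. Its metabolism in a
genome is governed by eleven genes that this package tracks as named slots:

* the synthetase cluster **pgsB, pgsC, pgsA, ywtC/pgsE, pgdS** — the
  membrane synthetase complex, the small fourth ORF of the cluster (called
  *ywtC* or *pgsE* depending on the annotation; we treat the two labels as
  one presence slot), and the downstream gamma-PGA peptidase;
* **racE**, the glutamate racemase supplying D-glutamate;
* **ggt**, the gamma-glutamyltransferase that exo-degrades the polymer;
* **pghB, pghC, pghL, pghZ**, prophage-derived gamma-PGA hydrolases.

Which of these genes a genome carries, and how they are arranged — order
along the chromosome, transcription direction, intergenic distance — is a
reproducible fingerprint that separates *B. subtilis*, *B. velezensis* and
*B. amyloliquefaciens* strains into cluster-architecture genotypes (G1–G7)
and finer subtypes (SG1.1, SG2.1, ...). `pgatyper` implements that
fingerprinting end to end: gene detection by protein homology, architecture
extraction, rule-based genotype assignment, substitution cataloging,
distance trees, and the ninhydrin-assay yield arithmetic used to quantify
gamma-PGA production.

## Gene detection by pairwise alignment

Detection is deliberately simple and fully specified, so results are
bit-reproducible:

* **Model.** Global affine-gap alignment (Gotoh three-state recurrence)
  of each annotated CDS translation against a reference protein per gene.
  A gap run of length $L$ costs $g_o + (L-1)\,g_e$ with defaults
  $g_o = -11$, $g_e = -1$ on BLOSUM62; `X` scores 0 against everything.
  Traceback tie-breaks are fixed (diagonal > up > left).
* **Identity.** Identical residue columns divided by aligned columns,
  where internal gap columns count in the denominator (terminal overhangs
  are excluded). A config switch
  (`identity_denominator = "ungapped"`) restricts the denominator to
  residue–residue columns, since published identity ranges rarely state
  their convention.
* **Presence thresholds.** `min_identity = 0.30`,
  `min_coverage = 0.50` (fraction of the *reference* covered by
  residue–residue columns). No published cutoff exists for this screen;
  0.30 sits above the 27–37% identity that the phage-derived hydrolase
  family shares with its more distant relatives, and the 50% coverage
  floor keeps pseudogenized or truncated CDS (common in public
  annotations) from counting as presence. Both are user-configurable and
  reported with every scan.
* **Assignment.** Each CDS can serve at most one gene slot; conflicts are
  resolved greedily by score with ties broken by genome order.

The dynamic-programming engine is verified in the test suite against an
exhaustive, memoisation-free enumeration of all gapped alignments for short
sequences, and against an independent aligner for longer ones.

## Architectures and distances

An architecture records gene order, strand pattern (in genome order, the
direction figures are drawn in), per-gene lengths and intergenic spacings.
The spacing convention is the **end-to-start gap**: negative values mean
overlap. This is the only convention consistent with using a
cluster-internal pgdS–ywtC distance on the order of 1–2 kb as a genotype
discriminator; start-to-start distances are available via
`intergenic_distance(convention = "start")` for sensitivity analysis.

## The genotype rule table

Genotypes and subtypes are declarative data, not code: a versioned YAML
document (`bacillus-pga-v1` is packaged) lists rules with required and
forbidden gene sets, optional order templates, strand patterns over
`{+, -, *}` and spacing windows. Evaluation is ordered with
first-match-wins — the simplest conflict resolution that makes results
reproducible. Three design points deserve explanation:

* **G3 before G2.** G2 and G3 have identical gene content (everything but
  *pghZ*); G3 is distinguished solely by a large pgdS–ywtC separation.
  Genotype rules therefore evaluate *all* their clauses, including spacing,
  and the packaged file lists G3 first so a far-separated-pgdS genome is
  never swallowed by G2. G2's gene content is encoded as "all gamma-PGA
  enzyme genes except *pghZ*", the reading that the G1-versus-G2 contrast
  (all eleven genes versus ten) supports.
* **Spacing windows, not point values.** Observed distances such as
  1720 bp are strain observations, not thresholds; packaged windows are
  ±10% around them so the rules are usable on new genomes.
* **Deterministic completion of subtype templates.** The published
  narrative specifies only some subtype discriminators (e.g. which gene
  blocks are transcribed in opposite directions). A rule table in which the
  unspecified parts are wildcards cannot support first-match-wins — every
  G1 genome would match the first G1 subtype. The packaged table therefore
  completes each subtype with a concrete, distinct order/strand template
  (the stated discriminators are kept verbatim; the completions are this
  package's own convention). The `*` wildcard remains fully supported for
  user-supplied rule sets, and wildcard clauses are flagged in the
  assignment evidence.

Genomes matching a genotype but none of its subtypes get subtype
`"unassigned"`; genomes matching no genotype are `"untyped"`. Both are
ordinary outcomes, not errors.

## Substitution catalogs

Variant calling is reference-anchored: after global alignment, every
mismatch column becomes an event positioned by the *reference* residue
index (`D74N` notation), so events aggregate by notation across hundreds of
strains. Insertions and deletions are kept in a separate table — they shift
query coordinates but never reference positions — and applying events plus
indels back to the reference reconstructs the query exactly (tested
property). Panel frequencies are always computed as `count / panel_size`
and formatted from that single number (two-decimal percentages); counts and
percentages are never reported independently of each other, which avoids
the internally inconsistent count/percentage pairs that hand-curated
variant tables tend to accumulate. Strains lacking a protein are excluded
from that protein's denominator.

## Trees

Published analyses of this gene family typically use ClustalW alignments
and maximum-likelihood trees with bootstrap. This package deliberately
replaces that pipeline with a self-contained, dependency-light equivalent
that supports the same qualitative claims (clustering, branch diversity):

* **MSA** by progressive alignment (pairwise identity distances, UPGMA
  guide tree, profile–profile affine alignment). A star alignment around
  the centroid is built as a second candidate and the better of the two
  under the affine sum-of-pairs score is returned, so the result provably
  never scores below the naive star baseline.
* **Distances**: p-distance with pairwise deletion — mismatches over
  columns where neither row is gapped. Pairwise deletion was chosen over
  complete deletion because one divergent, gap-rich sequence would
  otherwise discard columns for every pair.
* **Trees**: Saitou–Nei neighbor joining with deterministic tie-breaking
  (smallest label pair). Negative branch estimates are clamped to zero with
  the raw value retained in the `"clamped"` attribute. On additive
  matrices the generating topology and branch lengths are recovered
  exactly (tested on random 4–8 leaf trees).
* **Bootstrap**: columns resampled with replacement, NJ per replicate,
  support = percentage of replicates containing each internal split of the
  full-data tree. Everything is driven by one integer seed; two runs with
  the same seed are bit-identical.
* **Branch diversity**: `count_variants()` counts distinct sequence
  strings (haplotypes). Published "evolutionary branch" counts have no
  stated operational definition, so this proxy is reported instead and the
  two are not compared numerically.

Maximum-likelihood inference is out of scope by design; where a tree from
an ML tool is available it can be read with `read_newick()` and compared
split-by-split.

## The assay module

The ninhydrin quantification chain is: linear standard curve (OLS) →
glutamate back-calculation `x = (y - b) / m` → gamma-PGA content →
volumetric yield `content / volume`. The content step ships **two
variants** because the printed formula conventions in assay write-ups are
not mutually consistent: the default `"ratio"` variant computes
`glutamate * W / G` (the dimensionally coherent conversion via the
standard's glutamate-per-mass ratio, with W's unit declared explicitly by
the caller — grams and micrograms differ by 10^6 and are never guessed);
the `"literal"` variant keeps the printed form `glutamate / ((G/W) * 100)`
for fidelity. Every result records which variant produced it. OD600 is
carried through reports but used in no formula. Only the content → yield
step is asserted against published values, because upstream published
contents embed undocumented dilution factors that no stated formula
reproduces.

## The synthetic-data generator

All fixtures are generated, never stored. The generator defines the study
conditions used by the tests and the acceptance script:

* Reference proteins are random sequences with B. subtilis-like residue
  composition, first residue M, default lengths close to the real enzymes
  (pgsC smallest at 149 aa, ggt largest at 587 aa). These are length/
  composition stand-ins, not biological sequences.
* Genomes are back-translated with one fixed frequent-codon choice per
  residue (translation table 11, stop `taa`) and 43% GC filler —
  deterministic per seed, byte-identical across runs.
* Architecture templates are derived *from the rule table itself*
  (`template_for_label()`), with 150 bp default gaps and spacing-window
  midpoints where a rule constrains a pair, so rule set and generator are
  consistent by construction.
* Mutation plans plant substitutions at stated positions;
  `ceiling(fraction * n)` strains carry all events, making small-panel
  frequencies exact (0.75 on n = 4 is exactly 75.00%).

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: insertions/deletions and recombination
within genes, realistic codon usage and GC skew, pseudogenes and partial
annotations, origin-spanning features on circular chromosomes (the parser
rejects these explicitly), and contamination or mis-assembly. Detection
thresholds validated on planted panels should still be sanity-checked on
real annotation idiosyncrasies.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale by choice:
34 architecture templates with realistic protein lengths plus 64
gene-deletion perturbations; 1,000+ enumeration-verified alignment pairs
(length <= 6; the brute-force oracle is exponential); 10 panels of 200
strains for substitution recovery; 100 random 4–8 leaf additive trees;
1,000 bootstrap replicates on 4-taxon fixtures; 50 GenBank and 50 Newick
round-trips. Headline strain-collection counts from large public-genome
surveys (hundreds of GenBank genomes) are not reproduced here: they depend
on downloads and curation outside the package's scope, and are replaced by
the planted-ground-truth properties above.

Numerical conventions: distance-matrix asymmetry beyond 1e-9 is an error;
NJ branch lengths are written with 15 significant digits so Newick
round-trips preserve them to 1e-9; identity comparisons in tests use exact
arithmetic wherever the fixture permits it; all randomness flows from
explicit integer seeds (kept below 2^31).

## Known limitations

* Genotype rules match order/strand templates absolutely, not up to
  whole-genome reverse complement; a globally flipped assembly should be
  normalized upstream.
* The GenBank parser targets the feature subset this analysis needs (CDS
  with location, locus_tag, gene, product, translation); it is not a
  general-purpose flat-file reader (no fuzzy locations, no multi-span
  joins).
* Progressive MSA quality is adequate for closely related panels; for
  deep divergence a dedicated aligner will do better, and its output can
  be imported as gapped FASTA.
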