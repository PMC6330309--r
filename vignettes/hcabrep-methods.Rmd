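---
title: "Methods: heavy-chain-only repertoire analytics in hcabrep"
author: "hcabrep authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heavy-chain-only repertoire analytics in hcabrep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(hcabrep))
```

`hcabrep` analyses amino-acid V_H repertoires from heavy-chain-only
antibody (HCAb) discovery: germline annotation, somatic-hypermutation (SHM)
counting, CDR3 clonotype clustering, usage and assay statistics, and CDR
composition tests. This vignette records the models, the parameters that
matter, the numerical choices, and what the synthetic cohorts do and do not
establish. It states no empirical result beyond what the package's test
suite and `scripts/acceptance.R` themselves compute.

## Germline annotation

Reads are amino-acid V_H sequences. Each read is aligned against every
V-segment reference with `Biostrings::pairwiseAlignment` under one fixed,
reproducible scheme: BLOSUM62, affine gaps (opening 10, extension 1,
half-bit units), germline-global / query-local, so the full germline
segment span is consumed and the query contributes a substring. The
highest-scoring gene wins; ties break by higher identity, then
lexicographic gene name, making annotation deterministic and
order-invariant. Identity is matches over aligned (non-gap) columns.

Reads whose alignment spans fewer than `minAligned = 7` residues fail the
filter. This is the protein-level analogue (ceiling of 20/3) of discarding
reads with under 20 nucleotides of immunoglobulin-locus alignment, the
conventional NGS pre-filter for this assay class.

Region extraction projects the reference's IMGT-style boundaries (FR1,
CDR1, FR2, CDR2, FR3 as 0-based half-open intervals that tile a prefix of
the V gene) through the alignment's matched position pairs. The cut point
for a boundary *b* is the first aligned query residue at or beyond
germline index *b*; insertions therefore attach to the downstream region
and a one-residue insertion shifts all downstream boundaries by exactly
one. CDR3 runs from the end of projected FR3 to the start of the projected
J FR4 region; an empty or inverted CDR3 (e.g. a bare germline V with no J
segment) marks the read not annotatable rather than erroring the batch.

Two J-segment choices deserve explanation:

* **J genes are assigned on their FR4 span** (conserved W-G-x-G motif
  onward). The junction-proximal J residues lie inside CDR3, whose content
  is dominated by V(D)J junctional diversity; including them lets an
  unrelated J gene win by chance matches against the junction and corrupts
  the motif register. Anchoring on FR4 keeps the CDR3/FR4 boundary and the
  motif projection stable. J calls among J genes with near-identical FR4
  sequences remain ambiguous (they differ by one or two residues); the
  quantity the analyses consume — the residue observed at the motif
  position — is robust to that ambiguity.
* **The "position 101" residue is located structurally**, as the query
  residue aligned to the J gene's conserved motif tryptophan (or the
  engineered arginine of the variant J), not through a full Kabat
  numbering engine. This is robust to junction-length variation and is
  exactly the residue the Arg-variant J gene modifies. Kabat numbering
  engines are out of scope.

SHM is the count of amino-acid substitutions over aligned V-region
positions (FR1–FR3, CDR1/CDR2 included). Alignment gaps are excluded: the
underlying definition is "mismatches" from an amino-acid alignment, and
indel treatment is unstated in that convention, so the narrower
substitutions-only reading is used. A germline-identical V region gives 0
and identity 1 exactly.

For speed, aligned pairs are reconstructed from the alignment's range and
gap coordinates rather than from gapped strings (the string accessors cost
~30 ms per alignment, which is prohibitive at cohort scale); the
reconstruction is cross-checked against the string-based path in the test
suite.

## Clonotype clustering

CDR3 similarity is normalised Levenshtein,
`1 − lev(a, b) / max(|a|, |b|)`: symmetric, 1 exactly iff equal, and
well-defined across junction lengths (a same-length Hamming mode is
available). Families are single-linkage agglomerative clusters on distance
`1 − sim` cut at `1 − threshold` with threshold 0.8 — equivalently the
connected components of the 80%-similarity graph. Single linkage is the
default because "family" language implies transitive membership; complete
linkage and an optional same-V/J gate are configuration flags, off by
default since the underlying convention specifies neither. The partition
is invariant to input order (unique CDR3s are sorted before clustering).

Families are ranked by their fraction of total sample reads (rank 1
largest, ties by lexicographic representative CDR3, the representative
being the most abundant member's CDR3). Candidate selection walks families
in rank order taking up to `nPerFamily` most-abundant distinct sequences
until the budget is reached, deduplicating at the full-sequence level —
mirroring abundance-prioritised screening of unique V_H candidates.

## Repertoire statistics

* **Usage** is per unique pass-filter sequence by default ("percentage of
  antibodies" reads as molecule-level); read-weighting is a flag. Profiles
  zero-fill genes never assigned, so decoys always appear.
* **Limit of detection**: the maximum per-sample frequency attained by any
  decoy gene (reference genes absent from the genome) across samples;
  usage at or below it is unreliable. The statistic is monotone —
  adding samples can only raise it. On clean synthetic cohorts decoys are
  essentially never best-scoring and the LOD sits at 0; the rule's
  arithmetic is exercised on constructed profiles in the tests.
* **Averaging** across animals is an unweighted mean (each animal counts
  equally regardless of sequencing depth; depth-weighting is not stated in
  the underlying convention and is deliberately not applied).
* **ELISA**: signal divided by the mean background signal; positive iff
  the ratio is at least 30 ("a minimum of 30-fold" makes the boundary
  positive).
* **Campaign summaries** count a family antigen-specific if any member is
  ELISA-positive (the majority-vote alternative is not used; any-member is
  the weaker and stated-data-compatible reading). Cohort pooling
  reconstructs per-campaign lambda-positive counts from printed
  percentages as `round(pct × total / 100)` — the packaged table's
  reconstruction rule, which reproduces the published pooled count
  exactly.

## Composition statistics

Residues partition into hydrophobic {A,V,I,L,M,F,Y,W}, special cases
{C,G,P}, charged {R,H,K,D,E} and polar uncharged {S,T,N,Q}. Per antibody,
each CDR yields four class frequencies summing to 1 (12 per antibody);
group contrasts report `100 × (mean(A) − mean(B))` percentage points. Mean
(not median) differences are the default because "subtracting each
frequency" only aggregates coherently as means; medians are a flag.

The Mann–Whitney U test is two-sided. For groups of at most 8 the p-value
comes from full enumeration of the permutation distribution of U with
mid-ranks, so the exact path stays valid under ties; otherwise the
tie-corrected normal approximation with continuity correction (via
`wilcox.test`) is used. Degenerate cells (all pooled values identical) get
p = 1 by convention and are flagged. Raw p-values are reported across the
12 cells, matching the reporting convention for this analysis; a
Bonferroni column is emitted alongside for transparency.

Kyte–Doolittle profiles use the published 1982 scale, window 9, and a
linear weight variation model: weights fall linearly from 1 at the window
centre to `edgeWeight` at both ends and are normalised to sum to 1. The
edge weight of the reference implementation of that model is not published,
so the default is 1.0 (uniform window) with the edge weight exposed as a
parameter; a homopolymer profiles flat at the residue's scale value for
any edge weight, which pins the normalisation.

## The synthetic cohorts

`simulateRepertoire()` generates per-animal repertoires with full ground
truth. The default scenario *is* the study condition the analyses target:
10 animals × 2,000 sequences, 50 clonal families per animal with geometric
expansion (decay 0.08), junction lengths 9–18, V usage biased toward VH3/
VH4 genes (0.30/0.20/0.20/0.12/0.10/0.08 over six genes), 80% usage of the
Arg-variant J, lambda binding coupled to the realised FR4 residue
(P(λ|W) = 0.23, P(λ|R) = 0.007 — together with the J mixture these imply
~5% lambda binders, ~89% of binders carrying W and ~84% of non-binders
carrying R), and V-region SHM of 0.02 per residue (0.0145 for lambda
binders, 0.033 for antigen-specific sequences, giving ~25% vs. <5%
germline sequences over a 96-residue V region). Antigen specificity is
clonally structured: 30% of clones are reactive and members of reactive
clones are positive with probability 0.215/0.30, so the per-sequence
marginal is 21.5%.

Design choices worth recording:

* **V and J are drawn per sequence, the junction per clone.** Clone-level
  V draws would make the usage estimator's effective sample size the
  number of clones, which is incompatible with the ±0.02 usage-recovery
  property at these cohort sizes; the clonal signal the pipeline must
  recover (shared CDR3) is carried by the junction. The simulator is
  synthetic and this decoupling is explicit.
* **Junctions are drawn from a weighted residue alphabet**, enabling exact
  composition planting: the heavy-chain-only alphabet shifts CDR3 class
  totals by −8.7 (hydrophobic), +5.0 (charged), +3.7 (polar uncharged) and
  0.0 (special cases) percentage points against the light-chain-paired
  comparison alphabet. The special-cases delta is exactly zero so that
  "every affected class" is well defined in sign-recovery checks. D
  segments exist in the reference but are not embedded in junctions
  (D-gene calling is out of scope, and embedding them would break exact
  composition planting).
* **Clone-level variance.** Because junctions are clonal, composition
  group means computed over sequences have an effective sample size closer
  to the number of clones; per-seed CDR3 deltas therefore fluctuate around
  the planted values by roughly ±2 percentage points at the default sizes,
  and Mann–Whitney p-values on full-pipeline data are anti-conservative in
  the same way they are for real clonally-related repertoires. Recovery
  checks therefore assert sign and significance on pipeline data, and
  magnitude (±1.5 points) on independently drawn junctions.
* **ELISA separability.** Positive ratio draws lie in [40, 400], negative
  in [0.2, 5], disjoint around the 30-fold threshold, so planted labels
  are recovered exactly; noisy overlap is possible by supplying custom
  ranges but the invariant positive ≥ 30 > negative is enforced.
* **Reproducibility.** Per-animal sub-seeds derive from the master seed,
  so cohorts are bit-reproducible and animals order-independent; ELISA
  signal draws take their own seed and never affect labels.

The packaged germline reference (`toyGermlineSet()`) is synthetic:
IMGT-style names and architecture (6 V, 3 D, 6 J genes, FR/CDR boundaries,
one Arg-variant J), sequences hand-built around a canonical VH3 backbone —
not true IMGT alleles. Three decoy V genes (8+ substitutions from any real
gene, one deliberately close at 4 substitutions) support the limit-of-
detection rule.

What passing on synthetic data does *not* show: performance on real reads
with sequencing errors, indels from merging artifacts, allelic variation
beyond the toy reference, SHM hotspot structure (WRC/GYW motifs),
insertions/deletions from SHM, or nucleotide-level analyses — all out of
scope by design.

## Problem sizes and runtime

The test suite runs the full default cohort (10 × 2,000 plus the 5 × 1,000
comparison cohort) once in its acceptance checks, about two minutes in
total on one CPU; `scripts/acceptance.R` repeats the cohort computation
from scratch in about 1.5 minutes. Unit tests use cohorts of 40–600
sequences, which is ample for the exact checks (planted substitutions,
boundary cases, oracle equivalences) they perform.

## Known limitations

* Protein-level only; the optional nucleotide fields are inputs, not an
  analysis mode.
* J calls discriminate only as far as FR4 sequences differ; downstream
  analyses use the motif residue, not the J label.
* The Kabat-vs-structural labelling of the FR4 motif position is not
  adjudicated: the package anchors on the J motif residue and reports it
  as such.
* The small-sample exact Mann–Whitney path enumerates C(n1+n2, n1)
  assignments and is intended for n ≤ 8 per group, as configured.

## Session example

```{r example}
gl <- toyGermlineSet()
cfg <- defaultScenario(nAnimals = 1, nSequences = 100)
sim <- simulateRepertoire(cfg)
ann <- annotateRepertoire(sim$repertoire, gl)
table(vCall(ann))
fams <- clusterClonotypes(ann)
fams
head(shmCount(ann))
```
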