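---
title: "Methods: models, parameters, and design choices in tcrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in tcrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrkit)
```

`tcrkit` analyses bulk TCR beta-chain repertoires at the level of CDR3
amino-acid clonotypes: records of (CDR3 sequence, V gene, J gene,
abundance). This vignette explains the statistical procedures, the
parameters that matter, the behaviour of the synthetic-data generators,
and the choices made where the design was genuinely open. It states no
empirical result that the package's tests do not themselves compute.

## Input model and quality control

Four clonotype-table dialects are read into one canonical form: AIRR
Rearrangement TSV (`junction_aa`, `v_call`, `j_call`,
`duplicate_count`), MiXCR-style caller exports (count and sequence
columns recognised under the aliases `cloneCount`/`count`/`reads` and
`aaSeqCDR3`/`cdr3aa`/`CDR3.aa`, first match wins), bare CDR3 lists, and
generic CSV with a user-supplied column map. Two conventions are fixed at
ingestion: sequences are upper-cased, and a missing or zero count becomes
1 so that frequency-based statistics stay defined for formats that carry
no abundance. Rows without a CDR3 are dropped with a warning rather than
an error, because real caller exports routinely contain non-productive
rows.

Quality control applies five rules in a fixed order: (i) V/J allele
suffixes (`*NN`) are stripped to gene symbols; (ii) records lacking a V
or J gene are removed (skippable via `require_vj = FALSE`, which bare
CDR3-list input needs, since it cannot carry genes); (iii) CDR3s must
start with cysteine, end with phenylalanine or tryptophan, and contain no
stop codon (`*`) or frameshift marker (`_`) — the IMGT convention applied
at the amino-acid level, which is how "in-frame" is operationalised when
only amino-acid sequences are available; (iv) lengths must lie in 8..24;
(v) records sharing a CDR3 are merged. The order matters: allele collapse
must precede the merge, or allelic variants of one gene would be treated
as distinct and undercounted.

Two merge details are deliberate choices. Merged records **sum** their
counts, preserving clone-abundance mass for the diversity statistics
(the alternative, keeping only the majority record's count, would bias
frequencies downward). The surviving V/J annotation is that of the most
abundant merged record, with count ties broken by the lexicographically
smallest gene symbol — an arbitrary but deterministic rule. The QC report
satisfies an exact bookkeeping identity (output = input − per-rule drops
− merge absorptions), which the test suite verifies on randomized dirty
inputs; a record failing both a content rule and the length rule is
counted once, under the content rule.

## Diversity and clonality

The Renyi entropy of the clone frequency vector \(P\),
\[
H_\alpha = \frac{1}{1-\alpha}\log_b \sum_{i=1}^{N} P_i^{\alpha},
\]
is evaluated over the default order grid
\(\{0, 0.25, 0.5, 1, 2, 4, 8, 16, 32, \infty\}\), which spans the
conventional display range of the diversity curve. The three limit
orders are computed as exact special cases — \(\log_b N\) at
\(\alpha = 0\), Shannon at \(\alpha = 1\), \(-\log_b \max_i P_i\) at
\(\alpha = \infty\) — because the general formula is numerically
indeterminate there; other orders use a log-sum-exp so large
\(\alpha\) does not underflow. The logarithm base defaults to 2 (bits)
and is exposed as a parameter.

Clonality is \(1 - H_1 / \log_b N\), the complement of the Pielou
evenness: 0 for an even repertoire, near 1 under clonal dominance. At
\(N = 1\) the Pielou index divides by zero; the package defines the
clonality of a single-clonotype repertoire as 1, reading one clone as
maximal dominance.

Both statistics use count-weighted clone frequencies by default; a
`weighting = "unique"` option gives every unique sequence equal mass,
since either convention appears in the literature and inputs without
counts make the distinction moot.

## Sequence logos

Position weight matrices are built without pseudocounts over observed
letters only, so conserved positions read probability 1 exactly. The
top-100-frequency logo has no natural alignment when the selected
sequences differ in length; rather than impose one, the sequences are
grouped by length, the modal-length group's PWM is returned (ties toward
the shorter length), and all length groups remain available as an
attribute.

## Similarity network

The network workflow clusters sequences, then links within-cluster pairs
at Hamming distance < 3 — strictly less, so every edge has distance 1 or
2. Clustering is length-stratified single-linkage Hamming clustering
with `max_intra_distance = 2`, chosen to be consistent with the
downstream link rule: any pair eligible for an edge is necessarily
joined by the single-linkage pass, so the resulting edge set equals a
brute-force all-pairs Hamming thresholding (a property the tests check
exhaustively at 200 sequences). Because strata share one length, the
within-cluster multiple alignment reduces to the identity; hooks accept
externally produced cluster tables (`read_giana_clusters()`) and
alignments (the `alignment` argument of `build_network()`) for
variable-length extensions computed by dedicated tools.

Node weight combines two centrality notions. Raw betweenness and degree
live on incomparable scales, so each is min-max scaled **within its
connected component** before the combination
`0.5 * betweenness + 0.5 * degree` (coefficients exposed); a component in
which a statistic is constant — including isolated nodes — scores the
neutral 0.5. Communities come from walktrap random walks with the
algorithm's conventional walk length of 4, run under a caller-supplied
seed; isolated nodes become singleton communities so the result is
always a partition of all nodes. Community logos are frequency-weighted
PWMs, well-defined without alignment because community members share one
length by construction.

## Motif features and embedding

Each CDR3 of length \(L\) yields \(L - 2\) overlapping 3-mers; a sample
is the 8000-dimensional count vector over the amino-acid 3-mer universe
(k is parameterized but fixed at 3 throughout the standard workflow).
The cohort pipeline tracks an explicit stage
(`raw → sample_filtered → prevalence_filtered → mwu_filtered →
normalized`) and refuses out-of-order application, because the filters
are only meaningful in sequence.

* **Sample filter**: samples ranked by total motif count lose the top
  and bottom 20% tails. The tails are `ceiling(n * q)` samples, so any
  non-empty tail removes at least one sample even in small cohorts —
  a rank-based reading that stays defined at n = 3.
* **Prevalence filter**: a disease-specific motif should occur in the
  majority of that disease's samples; "more than 50%" is read as a
  strict inequality (present in exactly half is not a majority), with
  the threshold exposed.
* **Mann-Whitney filter**: per motif, disease-sample counts are compared
  against healthy-sample counts (a motif absent from the healthy matrix
  is compared against zeros) and kept when the two-sided P is at most
  0.05. Counts are compared after the sample-size filters; per-sample
  frequencies are available as an option.

The Mann-Whitney implementation is exact whenever \(nm \le 400\): motif
counts are tie-heavy, and the exact tie-aware permutation distribution of
U is computed by a counting recursion over (doubled, integer) midranks
rather than subset enumeration, which would be infeasible at those
sizes. The two-sided exact P is \(P(|U - nm/2| \ge |u_{obs} - nm/2|)\);
the permutation distribution is symmetric about \(nm/2\) under rank
reversal, so this coincides with the usual doubled one-sided tail while
remaining well-defined with ties. Larger samples use the normal
approximation with tie-corrected variance and continuity correction.
The test suite checks the exact branch against brute-force subset
enumeration for all \(n, m \le 8\) and the approximate branch against
`stats::wilcox.test`.

Z-score normalisation is per motif column with the population standard
deviation; zero-variance columns become zeros rather than NaN. The
column means and SDs are stored with the fitted embedding so new samples
are projected on exactly the training scale.

The default embedding backend is a diffusion map with potential
distances: a k-NN Gaussian kernel with adaptive per-point bandwidth (the
distance to the 5th neighbour), symmetrised and row-normalised into a
diffusion operator, powered `t = 3` steps, log-transformed into
potential coordinates, and reduced by classical metric scaling. The
defaults (knn = 5, t = 3) are small-cohort settings matching the tested
sample sizes; both are exposed. Classical scaling is sign-ambiguous, so
each axis is deterministically oriented (largest-magnitude loading
positive), making the fit reproducible without randomness; the seed is
recorded and guards pluggable backends, since `backend` accepts any
`function(X, n_components)` for substituting an external embedding
implementation.

Out-of-sample projection is a Nystrom-style kernel interpolation: the
aligned, Z-scored query is placed at the inverse-squared-distance
weighted average of its 15 nearest reference samples' coordinates. This
kernel was chosen over a Gaussian because it makes re-projection of a
reference sample reproduce its fitted position exactly (the distance-0
weight dominates), which is the self-consistency contract users expect
of "project my training data". An all-zero aligned vector carries no
information and falls back, with a warning, to the reference centroid.

## Annotation search

"At most one mismatch" is implemented as Levenshtein edit distance
\(\le 1\) — substitution, insertion, or deletion — matching the
fuzziness semantics of the full-text search engines this style of lookup
imitates; a substitutions-only (Hamming) mode is provided because both
readings are defensible. Lookup uses a deletion-variant index: every
reference sequence is keyed by itself and each of its single-deletion
forms, and a query probes its own variants. Any pair at edit distance
\(\le 1\) shares at least one such key, so candidate retrieval is
complete; candidates are then verified with a true edit-distance
computation, making the result contractually identical to a brute-force
scan (verified in tests against an independent dynamic-programming
oracle and a full `adist()` matrix at 500 x 2000 scale). Only the top
3000 clonotypes by frequency are queried by default, reflecting that
disease-associated clones are typically high-frequency; frequency ties
at the boundary break lexicographically for determinism. Enrichment
summaries count **unique** annotated query sequences per label, so a
query hitting two records with one label counts once.

## Synthetic data: what it emulates, what it does not

The generators exist so every module is testable offline, and their
defaults are the study conditions of the test suite. Sequences are
IMGT-conformant by construction (C anchor, F/W terminus at 9:1, interior
uniform over the 20 letters) with lengths uniform on 10..18 — the
central TRB range inside the 8..24 QC window. Clone sizes follow a
truncated discrete power law with exponent 2, reproducing the
heavy-tailed clonal composition real repertoires show; `geometric` and
`constant` (perfectly even) laws are available. Disease structure is
emulated by motif spike-ins: each configured 3-mer replaces a random
interior window (never the anchors) in a Bernoulli-chosen fraction of
clones, defaulting to probability 0.3 in the two-group embedding
cohorts, with a group named `healthy` never spiked. One RNG stream per
generator invocation, seeded from the config, makes every output
byte-reproducible.

What the simulator does **not** model: V(D)J recombination statistics
(no junctional bias, no generation-probability structure), nucleotide
sequences, sequencing error, or inter-sample clone sharing. Passing
tests therefore demonstrate algorithmic correctness and the recovery of
planted structure, not performance on real cohorts: in particular the
embedding's group-recovery result shows the pipeline can separate
motif-level signal of the configured strength, not that real diseases
separate this cleanly.

## Numerical conventions and degenerate inputs

* Frequencies always sum to 1 within 1e-9 after any operation that
  changes counts; empty repertoires are valid zero-row objects (with a
  warning when QC empties one).
* `renyi_entropy` validates its input simplex to 1e-6 and rejects
  negative orders; profiles of a single clonotype are identically zero.
* PWM rows, V/J usage, pairing tables and clonal compositions each
  normalise to 1 within 1e-9; the V-J pairing marginals reproduce the
  per-segment usage tables on fully annotated repertoires.
* Constant motif columns Z-score to zero; duplicate samples embed to
  identical coordinates.
* All frequency ties (top clones, annotation queries, merge genes)
  break lexicographically, so every pipeline stage is deterministic
  under a fixed seed.

## Problem sizes in the test suite

The suite exercises: QC bookkeeping on 150 randomized dirty repertoires;
Renyi monotonicity on 1000 random simplex draws; network-vs-brute-force
equality at 200 sequences; exact Mann-Whitney agreement with enumeration
for all group sizes up to 8 over 200 random tie-heavy vectors; fuzzy
search against a full scan at 500 queries x 2000 records; embedding
group recovery with 20 + 20 reference and 20 held-out samples of 300
clones each; and an end-to-end command-line run on a 5000-clone sample.
These sizes were chosen as the smallest at which each property is
non-trivially exercised, keeping the default test run fast while the
same code paths scale to full repertoires.

## Known limitations

* Hamming-based clustering cannot relate CDR3s of different lengths;
  the import hooks are the intended route for alignment-based cluster
  definitions.
* The diffusion-map backend is a stand-alone embedding with the same
  interface contract as heat-diffusion potential methods, not a
  re-derivation of any specific published algorithm; plug in an external
  implementation through the `backend` seam when exact correspondence
  matters.
* The annotation index assumes an in-memory reference; it is built for
  curated-database scale (hundreds of thousands of records), not for
  all-vs-all repertoire comparison.
* Diversity and clonality are within-sample statistics; overlap indices
  and clonotype tracking across samples are out of scope.
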