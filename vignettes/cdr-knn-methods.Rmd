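---
title: "Predicting antibody-antigen binding from CDR sequence distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting antibody-antigen binding from CDR sequence distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CDRknn)
```

## The problem

Antigen binding is dominated by an antibody's six complementarity-determining
regions (CDRs): the three hypervariable loops on the heavy chain and the
three on the light chain. High-throughput immunoglobulin sequencing produces
these six loops cheaply, but determining which antigen an antibody binds
still requires structures or experiments. CDRknn implements a purely
sequence-based classifier built on a simple hypothesis: antibodies with
similar CDR sequences tend to share binding behaviour against a given
antigen.

The unit of analysis is the antibody–antigen *pair*: one row of a pair
table holds the six CDR strings, twelve derived physicochemical features,
an opaque predicted-epitope string, an optional docking interface score,
the antigen identifier, and a binary binding label (GOOD = good affinity,
POOR = low affinity).

## The distance model

Two CDR strings are compared with a generalized Levenshtein distance: the
minimum total cost of insertions, deletions, and substitutions, computed by
the standard dynamic program. Two substitution-cost models are provided:

* **identity** — every mismatch and every indel costs 1 (the classic
  Levenshtein distance);
* **blosum62** — mismatch costs are derived from the BLOSUM62 similarity
  matrix, so conservative replacements (e.g. L→I) cost less than radical
  ones (e.g. L→D).

The similarity-to-cost transformation is a pinned design choice of this
package (the general idea of BLOSUM-derived costs admits many concrete
formulas). The default is

$$\mathrm{cost}(a,b) \;=\; \min\!\Big(1,\; \max\!\big(0,\; 1 -
\tfrac{2\,S_{ab}}{S_{aa}+S_{bb}}\big)\Big),$$

which is 0 on identity, increases as the pair score falls below the
self-scores, and is clamped to \([0,1]\) so BLOSUM costs are commensurate
with the identity model's unit mismatch. An alternative linear
normalization, \((S_{aa}+S_{bb})/2 - S_{ab}\) rescaled to \([0,1]\), is
selectable (`blosum62CostModel("linear")`), and every report records which
model produced it. The indel cost under both models defaults to 1, again to
match the identity mismatch scale. The embedded matrix is the standard
half-bit integer BLOSUM62 distributed with NCBI BLAST, checksummed at load
and cross-checked against an independent rendition in the test suite.

Antibody-level distance is the Euclidean norm over the six CDR-wise
distances, each CDR compared only with its equivalent (H1 with H1, ...,
L3 with L3):

$$d(p, q) \;=\; \sqrt{\textstyle\sum_{i=1}^{6} d_i(p_i, q_i)^2}.$$

Finally, pairs that involve *different antigens* receive a fixed additive
penalty of 1000. Within-antigen antibody distances are far below 1000 in
practice, so the penalty makes same-antigen training pairs dominate the
neighbourhood whenever any exist, while still permitting a deterministic
cross-antigen fallback for sparsely covered antigens (such predictions are
flagged in the evaluation report).

## The classifiers

**Weighted K-NN.** The K training pairs nearest to the query each vote
their own label with weight \(w(d) = 1/(d + \varepsilon)\),
\(\varepsilon = 10^{-8}\); the class with the larger summed weight wins.
The weight function is a package decision — the requirement is only that
nearer neighbours weigh more — and inverse distance is the simplest
monotone choice; \(\varepsilon\) exists so an exact duplicate (distance 0)
casts an effectively infinite, but finite-arithmetic, vote. Exact weight
ties predict GOOD (deterministic, configurable); distance ties at the K-th
rank keep earlier training rows (reproducibility). The default K is 2, the
best-performing setting.

**The 13-feature voting ensemble.** The "forest" is not a conventional
random forest: there is no bootstrapping, no feature subsampling, and no
impurity splitting. Each of 13 features — the CDR string distance plus
hydrophilicity and isoelectric point for each of the six CDRs — acts as one
"tree": a K-NN classifier over that single feature (absolute scalar
difference for the physicochemical features, both with the cross-antigen
penalty), casting one vote. The final label is the simple majority; 13
voters make a tie impossible, and even-sized ablation subsets fall back to
the GOOD tie rule. Per-tree K defaults to 2 for consistency with the main
classifier.

## Physicochemical features

The per-CDR features are computed from sequence alone:

* **Average hydrophilicity** — the mean of per-residue Hopp–Woods
  hydrophilicity values (scale units; configurable).
* **Net charge at pH 7** — a Henderson–Hasselbalch sum: the N-terminus and
  the H/K/R side chains contribute \(+1/(1+10^{\,\mathrm{pH}-pK_a})\), the
  C-terminus and D/E/C/Y contribute \(-1/(1+10^{\,pK_a-\mathrm{pH}})\).
  Cysteine and tyrosine are included as ionizable groups (standard
  practice; alternate pKa tables may drop them).
* **Isoelectric point** — the pH where the net charge is zero. The charge
  is strictly decreasing in pH and the termini guarantee a sign change, so
  bisection on \([0, 14]\) (tolerance \(10^{-4}\) on \(|charge|\)) finds
  the unique root.

The original data set computed these columns with a proprietary web
calculator whose constants are not published, so exact agreement with that
deposited CSV is not guaranteed; this package defaults to the EMBOSS pKa
set and the Hopp–Woods scale, both documented, reproducible from the
repository alone, and swappable (`pkaTable("lehninger")`, custom named
vectors). The ensemble consumes (hydrophilicity, pI), the pair recorded in
the operational column list; net charge is also exported for users who want
it as a feature.

## Labeling from docking scores

Docking-derived rows are labeled by banding the Rosetta interface score
(lower = better binding): scores above −8.0 are POOR outright, below −9.0
GOOD outright, and the closed interval \([-9, -8]\) is a REVIEW band that
the original protocol resolved by visual inspection of docked poses. The
endpoints are assigned to the REVIEW band (a literal reading of
"higher than"/"lower than"). Visual inspection is out of scope here:
`resolveReview()` ingests its outcome from a manual resolution file, or
applies a blanket rule (`drop`, `all_good`, `all_poor`), and records the
rule used in a provenance column. REVIEW rows are refused by training and
evaluation until resolved.

## Evaluation

`loocv()` holds out each pair in turn, trains on the remaining \(n-1\)
pairs, and predicts the held-out pair; accuracy is the fraction of correct
predictions, reported per antigen and overall (the per-antigen accuracies,
weighted by pair counts, reproduce the overall value exactly). The
training pool is globally pooled across antigens — the fixed penalty is
what keeps neighbourhoods within an antigen — because the evaluation is
"per antigen" through the penalty rather than through hard partitioning;
a strict per-antigen pool (`restrictToAntigen = TRUE`) is available for
sensitivity analysis and agrees with the pooled run whenever every antigen
has at least K labeled pairs. Everything is deterministic: rerunning on the
same table and configuration reproduces the report byte-for-byte.

## The synthetic-data generator

Real pair tables require docking pipelines or database extractions, so the
package carries a generator that emulates the data set's structure: for
each antigen a GOOD-binder archetype antibody is drawn uniformly, and a
POOR archetype is derived from it by substituting exactly `separation`
positions per CDR; each record copies its class archetype with i.i.d.
per-position substitutions; labels can be flipped at a noise rate;
interface scores are drawn from per-class normal bands; and the feature
columns are computed by the same code path as `featurizeTable()`, so stored
values always match recomputation. Defaults are the package's study
conditions: 57 antigens × 20 pairs (the antigen count of the collated data
set, at a desk-scale number of pairs per antigen), CDR lengths 8, 8, 12
(heavy) and 11, 7, 9 (light) — typical immunoglobulin loop lengths —
separation 4, mutation rate 0.02, no label noise, balanced classes, and
score bands \(N(-10, 0.3)\) / \(N(-7, 0.3)\) that keep three standard
deviations clear of the review interval. Scores are drawn from the band of
the record's final (post-noise) label, so score-based relabeling
round-trips the stored label; under the default noise of 0 the distinction
from the pre-noise class never arises.

The default mutation model is substitutions-only, which keeps
archetype-to-record distances predictable; an indel mode exists for stress
tests. What the generator does *not* emulate: germline structure, somatic
hypermutation hotspots, shared lineages between antigens, epitope overlap,
and the extreme per-antigen class imbalance of real repertoire extractions
(it can be approximated by setting `classBalance` near 0 or 1). Passing
recovery tests on this generator therefore demonstrates that the estimator
and its implementation are sound under the stated model — not that real
antibody repertoires are this separable; the original study's ~82% on real
data versus near-perfect recovery on clean synthetic archetypes illustrates
the gap.

## Numerical and design notes

* The edit-distance dynamic program runs in compiled code; all-pairs
  distance matrices deduplicate repeated CDR strings first. The test suite
  validates the DP against an exhaustive edit-script enumeration oracle
  (plain recursion, no memoization) on every string pair up to length 5
  over a four-letter alphabet, under both cost models.
* Problem sizes in tests were chosen at desk scale: the recovery and
  permutation-null experiments use the full 57 × 20 default table; the
  mutation-rate monotonicity sweep uses 6 antigens × 10 pairs over 10 seeds
  per rate, at rates (0.05, 0.6, 0.8) spanning clean archetypes through
  near-random sequences.
* Unknown residues (`X`) are rejected by default; a lenient mode
  (`allowX`) scores `X` against everything at the model's average mismatch
  cost, since no principled substitution cost exists for it.
* Degenerate inputs: empty strings are legal in `editDistance` (pure indel
  cost) but CDR fields of a validated table must be non-empty; `k` larger
  than the training pool is an error rather than a silent truncation.
* Exact weight ties, vote ties, and K-th-rank distance ties are all broken
  deterministically (GOOD / GOOD / earlier row), so results are
  reproducible to the byte and permutation-invariant up to the documented
  rules.
* The label vocabulary of deposited CSVs varies ("YES", "good affinity",
  ...); the reader canonicalizes through a configurable synonym map and the
  writer emits "YES"/"NO" by default.

## Known limitations

* The BLOSUM-to-cost transformation and the K-NN weight function are
  package-pinned choices among several defensible ones; headline accuracies
  on external data will depend mildly on them, which is why every report
  carries a configuration fingerprint.
* Physicochemical columns may differ from externally computed ones if the
  external tool used different pKa constants or hydrophilicity scales;
  recompute with `featurizeTable()` for internal consistency.
* The method predicts a binary class per antibody-antigen pair; it does not
  rank antigens for an antibody, estimate affinities, or model epitopes
  (the epitope column is carried opaquely).
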