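---
title: "Selective voting ensembles for heterogeneous biomarker cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective voting ensembles for heterogeneous biomarker cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selvote)
```

## The model

`selvote` addresses a two-group classification setting where the interesting
output is not the label but the disagreement structure: which patients a
biomarker panel votes *against* their clinical label, and which marker
combinations drive that vote.

Given `m ≥ 2` markers on `n` subjects labelled gingivitis (`−1`) or
periodontitis (`+1`), concentrations are log-transformed and z-scored per
marker over all `n` samples. One analysis realization partitions the samples
into disjoint test folds of size `k1` (a fresh uniform permutation cut into
consecutive windows; the last fold holds `n mod k1` samples when `k1` does
not divide `n`). For every fold and every unordered marker pair `(i, j)` a
base classifier is trained on the fold's complement using only those two
markers, and casts one vote — gingivitis or periodontitis — on each held-out
sample. Each sample is held out exactly once per realization and therefore
accrues exactly `m(m−1)/2` votes; the per-realization label is the vote
majority, with equal counts recorded as a tie. The whole procedure is
repeated `Nb` times with independent permutations.

Aggregating over realizations yields, per sample `k`:

* the **proclivity** `G_votes(k) = Σ_r υ_g(r,k) / (Nb · m(m−1)/2)` and its
  complement `P_votes(k)`; votes are summed in integer arithmetic and
  divided once, so the pair sums to 1 exactly;
* the **persistent ensemble sets** `σ_g*(k)` and `σ_p*(k)`: the marker pairs
  that cast the same vote for `k` in all `Nb` realizations (a strict
  intersection — pairs that ever switched belong to neither);
* the **aggregate label**: the majority of the per-realization labels, with
  tie realizations contributing nothing.

The **consensus map** compares persistent sets between samples:
`τ(i,j) = |σ_g*(i) ∩ σ_g*(j)|` within the gingivitis group,
`|σ_p*(i) ∩ σ_p*(j)|` within the periodontitis group, and
`|σ_g*(i) ∩ σ_p*(j)|` between a gingivitis-labelled `i` and a
periodontitis-labelled `j`. The alternative cross-pairing (the gingivitis
set of the periodontitis sample) is deliberately not computed. Diagonal
cells are undefined by the formula; for display we fill them with the size
of the sample's own-group set and exclude them from all statistics. Note a
consequence of the definition worth stating explicitly: on a perfectly
separable cohort *all three* regions saturate at `m(m−1)/2`, because a pair
that consistently votes a gingivitis sample G also consistently votes a
periodontitis sample P. Sparse, contrasting regions arise only when groups
overlap.

A **mismatch sample** is one whose per-realization label disagrees with its
clinical label in a strict majority of non-tie realizations. Ties are
excluded from that denominator because they carry no directional evidence;
they are randomly resolved (probability ½ each way, seeded) only when
computing accuracy-type metrics, which need hard labels.

## Base classifiers and their numerical guards

Four interchangeable kinds share one train/predict contract:

| kind | fit | guard |
|------|-----|-------|
| `lda` | class means, pooled covariance, proportion priors | Cholesky solve; singular pooled covariance is an error |
| `qda` | per-class covariances | diagonal-target shrinkage `(1−γ)Σ + γ·diag(Σ)`, `γ = 1e−4` escalated ×10 until positive definite |
| `nb`  | per-class, per-feature Gaussian mean/variance | variance floor `1e−9` |
| `svm` | linear soft-margin SVM (`e1071`), `C = 1` | — |

LDA, QDA and NB are evaluated from their closed-form Gaussian discriminants,
which makes the tie rule and the shrinkage exactly as documented; the SVM
delegates to `e1071::svm` because a well-tested quadratic-programming solver
is the right tool there. Decision ties — posteriors exactly equal, or an SVM
decision value of exactly 0 — deterministically predict `+1`
(periodontitis). Any fixed rule works for this measure-zero event;
determinism is what matters. Prediction by LDA/QDA/NB is equivariant under
per-feature affine rescaling applied to both training and test data; the
SVM with fixed `C` is not, which is one reason the pipeline insists on
z-scored inputs.

Training requires at least two members of each class. A fold permutation
that starves a training set is re-drawn (with a warning, capped at 100
attempts); at the default cohort shape (40/40, `k1 = 10`) this cannot
trigger, but small synthetic cohorts can hit it.

## Tunable parameters

* `Nb` (realizations, default **1000**): the reference analysis depth. Tests
  and examples in this package run at `Nb` between 20 and 100, which keeps
  the full suite under a minute of ensemble computation while leaving
  proclivity standard errors of a few percent; `Nb = 1000` remains the
  shipped default for real analyses.
* `k1` (fold size, default **10**): leave-10-out on 80 subjects gives 8
  folds. The method assumes `k2 = n − k1 >> k1`; the package warns when
  `k1 > n/4` rather than refusing.
* `classifier` (default `lda`), `cost` (SVM `C`, default 1): hyperparameters
  the method itself leaves open; defaults are the minimal faithful choices.
* `seed`: one seeded generator drives all permutations; results are
  bit-reproducible given the seed, and every output artifact records it.
* `consistency` (persistent sets, default **1**): the strict intersection
  can empty `σ*` for borderline samples at large `Nb`; a fraction below 1
  relaxes membership to "voted that way in ≥ `consistency·Nb` realizations".
  Off by default because the strict rule is the reference definition.

Normalization is global — computed once over all `n` samples before the
cross-validation loop, as the procedure specifies — not per training fold.
This is a deliberate fidelity choice and a known source of mild information
leakage between folds; with `n = 80` and two moments per marker the effect
is small, but comparisons against fold-local normalization schemes should
keep it in mind. The log base is natural; base choice cancels in z-scores.
Sample SDs use the `n − 1` denominator.

## The synthetic cohort generator

No patient-level data are distributed with the method, so the generator is
the package's test bed. It draws each marker from a log-normal law whose
`(μ, σ)` are moment-matched to published group-level means and SDs
(`σ² = ln(1 + S²/M²)`, `μ = ln M − σ²/2`), reproducing three qualitative
features of real salivary panels: strictly positive support, positive skew,
and SDs of the order of the means. The default moments are those of the
four-marker gingivitis/periodontitis panel (e.g. gingivitis IL-1β
29.6 ± 49.5, periodontitis MMP-8 397.9 ± 302.1), with 40 subjects per group.
A gamma family with the same two moments is available behind a flag.

What the generator does **not** emulate: between-marker correlations (none
are published; markers are independent by default, and a Gaussian-copula
correlation option exists precisely so experiments are not artificially
easy), batch or assay effects, and any covariate structure (age, smoking).
Passing tests on synthetic cohorts therefore demonstrates correctness of the
algorithmic machinery and recoverability of *planted* structure — not
clinical performance on real saliva.

Planted swaps model the biologically discordant subpopulation: a fraction of
each group (default 0; 0.2 in the recovery experiments, mirroring the ~20%
discordant subpopulation such cohorts can harbor) keeps its nominal clinical
label but is drawn from the other group's distribution. Mismatch detection
is then measured as recall of the swapped samples and false-flag rate on the
rest. At a log-scale group separation of ≥ 4 pooled SDs and `Nb = 100`, the
suite requires ≥ 80% recall with < 5% false flags; in practice recovery at
that separation is essentially perfect.

## Problem sizes and determinism

The shipped test suite exercises cohorts of 8–80 subjects, 2–6 markers, and
`Nb` up to 100; generator moment-recovery checks draw 10⁵ samples per group.
These sizes were chosen so that every statistical assertion sits at least
three standard errors away from its threshold under the fixed seeds while
the whole suite completes in well under a minute. Two runs with identical
configuration produce byte-identical proclivity tables, consensus matrices
and metrics files; this is asserted, not assumed.

## Known limitations

* The strict persistent-set intersection is brittle at very large `Nb`
  (one discordant realization in 10⁴ empties a set); use `consistency < 1`
  if that matters for your cohort.
* Pairwise feature subsets only: triples or larger ensembles, weighted
  voting and stacking are out of scope.
* Two groups only, and the positive class is fixed to periodontitis (`+1`)
  for sensitivity/specificity; the orientation is configurable in
  `performance()`.
* Global z-normalization leaks fold information by design (fidelity to the
  stated procedure); see above.
* With `m` markers the ensemble-set bitmask representation caps `m` at 8
  (30 pairs), comfortably above any published salivary panel but not
  suitable for omics-scale feature sets — which the voting scheme's
  exhaustive pair enumeration would not scale to anyway.
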