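---
title: "Models and methods: semantic relatedness and retroactive memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: semantic relatedness and retroactive memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retromem)
```

## The scientific problem

In paired-associate cued recall, a person learns word pairs (a *cue* and a
*target*), later learns a second list derived from the first, and is finally
tested on the original list. Whether the second list weakens the first
(retroactive interference, RI) or strengthens it (retroactive facilitation,
RF) has been argued to depend on the *semantic relatedness* between the old
and new material. retromem implements the full analysis pipeline for this
kind of experiment: relatedness metrics over free-association networks and
word embeddings, a counterbalanced two-list design generator, per-pair
memorability and joint-retrieval dependence statistics, smoothed bivariate
"Osgood" surfaces with cluster permutation inference, and the supporting
repeated-measures statistics — together with a synthetic-data generator so
that every stage is testable without any external download.

The design unit is a **quartet** {cue, Δcue, target, Δtarget}: the base pair
is cue–target; the secondary pair keeps, replaces, or swaps words according
to five within-subject conditions (`no_delta`, `delta_target`, `delta_cue`,
`delta_both`, `control`). A stimulus set holds 45 quartets built from 90
relation pairs, arranged on a 3×3 grid of cue-relatedness × target-
relatedness terciles with 5 quartets per cell, and conditions rotate over
the five quartet slots of each cell so that every block of five subjects
realizes a complete counterbalance (200 subjects ⇒ 40 per quartet ×
condition).

## Relatedness metrics

All network metrics run on a directed graph whose edge weights are
associative strengths (AS), the probability that one word evokes another in
free association. Conventions:

* **Backward / forward AS** — `as_strength(net, a, b, "backward")` is the
  edge `b → a`; absent edges are 0 (norms are sparse by construction),
  unknown words are errors.
* **Backward mediator strength** — the summed strength of all two-step
  routes `new → m → base`; mediators equal to either endpoint are excluded
  (the convention is ours; a max-product variant is available).
* **Weighted path length** — Dijkstra on edge weights `1 − AS`; unreachable
  or longer-than-cap paths are reported as the cap (default 6). A hop-first
  variant is available behind `criterion = "hops"`.
* **Spreading activation** — outgoing AS at every node renormalized to sum
  to one, once and statically; all directed walks of length ≤ 3 contribute
  the product of their renormalized weights. Walks may revisit nodes
  (`allow_revisits = FALSE` restricts to node-simple walks); renormalizing
  per node once, rather than per step, is the interpretation we fixed and
  flag.
* **Cosine similarity** — over pretrained embedding vectors read from the
  standard word-per-line text format.

`relatedness_profile()` bundles all metrics per pair, representing
missingness (a word absent from a resource) as `NA`, never as zero.

## The generative model of the synthetic data

`simulate_experiment()` encodes a *reminder* account of relatedness effects
as an explicit generative model. For a shown (subject, pair) with
condition-appropriate relatedness `rel` (target relatedness under
`delta_target`, cue relatedness under `delta_cue`, their sum under
`delta_both`, 1 under `no_delta`):

* a reminder occurs with probability `plogis(gamma0 + gamma1 * rel)`;
* the base-test success probability is
  `plogis(beta0 + beta_cond + beta_rel * rel + delta * R − phi * [48hr] −
  kappa * [delta_target ∧ 5min])`;
* given a reminder, the base and secondary outcomes share a latent
  bivariate-normal draw with correlation `rho` (this is what produces
  joint-retrieval dependence); without one they are independent;
* trials to criterion are `1 + Geometric(plogis(lambda0 + lambda1 * rel))`
  in retrieval mode;
* a failed base test in `delta_target` produces the secondary target as an
  intrusion with probability `iota`.

Two modelling choices are worth flagging. The secondary-test success
probability mirrors the base model (`beta0 + beta_rel*rel + delta*R −
phi*[48hr]`) because no separate contract exists for it, and `beta_rel`
enters the recall logit directly so that a relatedness slope exists even
when the reminder channel is switched off. Short-delay interference is a
retrieval-stage penalty `kappa` (applied only in `delta_target` at the 5-min
delay), a deliberate modelling stance — temporary retrieval impairment
rather than trace weakening. Reminders are drawn per (subject, pair), not
per trial, because only final-test outcomes are analysed.

The `paper_stylized` preset (the `sim_params()` defaults) was tuned once so
that simulated condition-level memorability at the long delay follows
no_delta > delta_cue > delta_target > delta_both > control, the qualitative
ordering expected under high overall relatedness; the `null` preset removes
every effect and exists for calibration studies. What the generator does
*not* emulate: real lexical idiosyncrasies (word frequency, length,
emotionality), response-time structure, subject-level heterogeneity in the
logit parameters, or fatigue across the session. Passing tests on synthetic
data therefore certify the *pipeline*, not any empirical claim about human
memory.

## Behavioral metrics

**Memorability** is the across-subject proportion of correct base-pair
recall per (pair, condition); the retroactive effect `delta_m` subtracts the
same pair's control proportion. **Dependence** of a base/secondary duo is
the proportion of aligned subjects with both outcomes equal (both recalled
or both forgotten) — equivalently one minus the normalized Hamming distance;
between floor and ceiling it is dissociable from memorability.

Each pair's dependence is referenced to a **mismatched-duo null**: its base
outcomes paired against every other pair's secondary outcomes within the
same condition. Because the counterbalance assigns different subject subsets
to different rotation offsets, mismatched duos are aligned by subject order
within each pair's own subject set (truncated to the common length); this is
the only alignment under which all 44 mismatched duos exist. The exceedance
criterion asks whether the true duo beats all but one mismatched value — a
fraction 43/44 ≈ 0.977 for a 45-pair set. The tail convention behind
translating this rank criterion into an α level is ambiguous (1/44 ≈ 0.023
one-sided, 2/44 ≈ 0.045 with a rank correction), so the package reports the
criterion fraction and the per-experiment mean threshold and leaves α
derivation to the user.

Subject exclusion removes overall accuracy below the across-subject mean
minus 4 standard deviations (no exclusions when the variance is zero), with
an optional study-only rule that also drops subjects with no correct
base-pair responses. Intrusions are exact string matches of the base-test
response against the secondary-list target after case-folding and trimming;
no typo tolerance is applied because no scoring rule is specified for it.

## The smoothed surface and its permutation test

The change-both condition asks a bivariate question: how does the
retroactive effect vary over (target relatedness, cue relatedness)? With 45
scattered pairs the surface must be smoothed, and smoothing must cover the
gaps between stimuli.

`smooth_scattered()` bins points to a regular grid (default 64×64 with a 2%
margin; cell value = mean, cell weight = count) and minimizes

$$ \|W^{1/2}(y - z)\|^2 + s\,\|Lz\|^2 $$

where `L` is the Neumann second-difference Laplacian whose eigenbasis is the
2-D discrete cosine transform. Empty cells carry zero weight and are filled
by the penalty. The normal equations `(W + sL'L) z = Wy` are solved exactly
by a sparse Cholesky factorization; because permutations move values but not
coordinates, the factor is computed once per dataset and reused across all
permutations, which is what makes 1000 re-smooths cheap. Robustness is an
outer loop of bisquare reweighting on MAD-studentized residuals (3
iterations by default; the exact robust-weight schedule of classic
implementations is not published, and our studentization omits leverage).
With robustness off the smoother is exactly affine in the data, preserves
constants, interpolates as `s → 0`, and tends to the weighted mean as
`s → ∞` — all of which the test suite asserts.

The smoothing level is expressed as a fraction of the input space: with
`s_frac = 0.40` (the default) the equivalent-kernel half-width is set to
40% of the grid extent by inverting the smoother's frequency response
(`s = λ(π/h)^{-2}`, `h = s_frac · n` cells). A raw `s` can be passed
directly instead for users who want to quote a specific smoothing factor
(e.g. 0.37 or 0.43); we deliberately do not claim numerical equivalence with
any particular legacy implementation, whose gridding conventions are not
printed.

`cluster_permutation()` then tests where the condition-minus-control surface
differs from chance:

1. Under the null, condition labels are scrambled. The default `scramble`
   scheme pools the per-pair condition and control memorability values and
   randomly reassigns which value fell in which condition — the literal
   reading of scrambling condition membership. Two alternatives are flagged:
   `sign_flip` (within-pair label swap) and `reshuffle` (differences
   permuted across coordinates). We measured the sign-flip variant and found
   its power against a compact planted effect capped well below the scramble
   scheme — where only *k* pairs support a region, a within-pair swap cannot
   produce a tail probability below 2^−k, and its local null variance is
   inflated by the planted values themselves — while both schemes are
   equally calibrated under the null; this measurement is why `scramble` is
   the default.
2. Pointwise above/below thresholds are the `1 − α` and `α` cell-wise
   quantiles (default α = 0.01 per tail) of the permuted *smoothed*
   surfaces, so thresholds track the local variance of the smoothed field.
   The alternative order — thresholding the unsmoothed permuted values and
   then smoothing the threshold grids — is implemented behind
   `threshold_order = "threshold_then_smooth"`; it references the smoothed
   surface to single-pair variability, which is an order of magnitude wider,
   and we measured essentially zero power for it, so it is not the default.
3. Clusters are 4-connected runs of cells (8-connectivity flagged) where the
   true surface exceeds a threshold, restricted to the data-supported region
   (cells within a few cells of at least one pair; outside support the
   surface is pure extrapolation). Each cluster's p-value is the fraction of
   permutations whose *maximum* suprathreshold cluster size — pooled over
   both polarities — reaches the cluster's size. Pooling polarities makes
   "any cluster significant at α" a familywise statement at rate ≈ α; an
   optional `(count+1)/(B+1)` correction is available.

At the sizes used in the test suite (a 64×64 grid, 200–500 permutations) the
measured familywise rate under null simulated experiments is consistent with
5%, and a +0.3 memorability effect planted in the top-tercile grid cell
(five pairs, with each memorability value estimated from 200 simulated
subjects) is recovered as a significant overlapping cluster in over 90% of
runs. Those problem sizes — 100 null experiments at 200 permutations for
calibration, 50 planted runs at 500 permutations for recovery — are the
package's chosen Monte-Carlo design points for its own validation.

## Supporting statistics

One-way repeated-measures ANOVA uses the textbook within-subject
decomposition; when a Mauchly test rejects sphericity at 0.05 (the pre-test
and its level are configurable, since the choice is conventional), the
degrees of freedom are multiplied by the Huynh–Feldt epsilon (computed from
the Greenhouse–Geisser epsilon and clamped to at most 1). Pairwise
within-subject t-tests over the 10 condition contrasts form one
Benjamini–Hochberg family. Item-level regressions are ordinary least
squares with pointwise (not simultaneous) 95% t-bands, the change-both
analyses using additive cue+target relatedness as the predictor. Partial
correlations are residual correlations with t-tests on n − 3 degrees of
freedom.

## Degenerate inputs and tie-breaks

Tercile ties in stimulus construction are broken by a stable sort on
(relatedness, word), making the grid reproducible from (input, seed). A
zero-variance accuracy distribution excludes nobody. A zero-variance paired
difference gives p = 1 when its mean is zero and is flagged degenerate
otherwise. Dependence requires aligned, equal-length outcome vectors. The
smoother rejects fewer than 5 points and degenerate spans. Cluster p-values
with fewer than 100 permutations require an explicit opt-in.

## Limitations

The association-network stand-in is a sparse random graph with planted
chains, not a real free-association database; the loader accepts the real
TSV format when a user supplies one. Embedding training is out of scope —
vectors are consumed, never fitted. The empirical statistics of any
particular deposited dataset can be recomputed only through the explicit
column-mapping adapter (`read_outcome_export()`), never fabricated. The
generative model is a convenience for validation and power analysis; its
parameters are not fitted to data, and no likelihood machinery is provided.
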