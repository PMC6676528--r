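---
title: "A branching-process model of polyploidy, fractionation and homolog similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A branching-process model of polyploidy, fractionation and homolog similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdfrac)
```

## The model

Whole-genome doubling (WGD) or tripling (WGT) copies every gene of a genome
`r` = 2 or 3 times; in the generations that follow, most of the extra copies
are lost again — *fractionation*. `wgdfrac` models a succession of such
events as a discrete-generation Galton–Watson branching process. Generation
`i` holds `M_i` genes; at event `i` each gene is replaced by `r_i` copies of
which `k` survive to the next event with probability `u_k^(i)`
(`k = 0, …, r_i`). The `u` vector plays the formal role of an offspring
distribution, but its biological reading is survival through the inter-event
interval: all genes duplicate synchronously at the event, and loss happens
between events. Event times are real numbers (My before present) carried
alongside the integer generation index; they do not enter the branching
process itself, only the rate calculations and the observation model.

Two genes observed at the present form an *i-pair* when their most recent
common ancestor was replaced at generation `i`: paralog pairs within one
genome, ortholog pairs across two genomes when the MRCA predates or equals
the speciation. The package computes the expected number of i-pairs in
closed form by products of moments:

* the mean survivor count per gene at event `i` is `mu_i = sum(k u_k)`;
* the expected surviving pairs created per gene at event `i` is
  `c_i = sum(choose(k, 2) u_k)`;
* `E(N_i) = M_1 · prod_{j<i} mu_j · c_i · prod_{j>i} mu_j^2`,

the squared factor expressing that the two members of a pair found
independent descendant lineages. With `r = 2` and `u_0 = 0` everywhere this
collapses to the familiar `prod(1+u) · u · prod(1+u)^2` form, and with all
`u_2` equal to `u` to `u(1+u)^(2n−i−1)` where `n` counts WGD events. The
expected unpaired genes (no surviving partner at any level) are
`E(M*) = M_1 prod u_1^(i)`, exact under the no-lineage-extinction
constraint `u_0 = 0`; with `u_0 > 0` side-branch extinction creates extra
singletons that this product does not count, which is why the package's
simulator checks use `u_0 = 0` when validating it.

### Speciation

A speciation is treated as a ploidy-2 event that places one copy of each
gene in each daughter genome. Its survival vector `(u_0, u_1, u_2)` encodes
joint survival over the following interval: both copies with probability
`u_2`, exactly one (equally likely either genome) with `u_1`. The constants
in the ortholog expectations are derived from this structure rather than
hard-coded: the per-genome marginal copy expectation is `m = u_1/2 + u_2`,
so a pre-speciation i-pair yields `2 m^2 · P_A P_B` cross-genome pairs in
expectation (`P_A`, `P_B` the mean-products of post-speciation WGDs — the
amplification factors), while an s-origin pair needs both copies of one gene
and so carries `u_2 · P_A P_B`. With `u_0 = 0` the familiar constants
appear: `2 m^2 = (1+u_2)^2/2` (the "1/2") and, when the two genomes'
post-speciation losses are modelled as independent — a binomial survival
vector `((1−m)^2, 2m(1−m), m^2)` — the s-origin coefficient becomes
`m^2 = (1+u)^2/4`, the "1/4". Both regimes are expressible through the one
speciation survival vector, and the simulator realises exactly the same
generative story, so closed forms and Monte-Carlo means agree by
construction, not by tuning.

### Ortholog-unpaired genes

For scenarios the package also provides a closed form for the expected
number of observed genes with no cross-genome partner, needed to close the
identifiability gap in survival estimation (below). An observed A-gene is
ortholog-unpaired exactly when genome B kept no observed descendant of its
generation-1 root. Writing `G` for the probability generating function of
the gene count at the speciation generation (composition of the shared
events' survival pgfs) and `z_B` for the probability that one
post-speciation B copy leaves nothing observed,
`E = M_1 (alpha_A G'(beta_B) + alpha_B G'(beta_A))` with
`beta_B = u_0 + u_1(1+z_B)/2 + u_2 z_B` and
`alpha_A = (u_1/2) w_A + u_2 w_A z_B`. This expectation is validated
against the simulator in the test suite. It is one concrete rendering of
the idea that the unpaired-gene count can support one extra estimated
parameter; other renderings (e.g. per-genome singleton counts) would be
possible, and the cell is therefore optional.

## The observation model

Pair similarities (proportion of identical nucleotides) decay approximately
exponentially with pair age: `p(t) = C e^(−λt)`, clipped above at 1 and not
clipped below — a remote event may genuinely fall below detectability.
`decay_model()` defaults to `C = 1` (identical sequences at age zero) and
`λ = 0.09` per My, the amplitude-1 version of the empirical trend printed
for the Solanaceae-type data this package emulates. Note that with
`λ = 0.09` any event older than ~100 My maps to numerically zero
similarity; the shipped fixture configurations, which emulate chronologies
spanning 36–130 My, therefore set `λ = 0.0045` explicitly so that component
means land between 0.55 and 0.9, where real syntenic-pair histograms have
them. Component standard deviations scale linearly with the mean
(`sd_model()`, default `0.12 − 0.10·mean`, i.e. sd 0.025 at similarity
0.95 and 0.07 at 0.5); variance is otherwise a free per-component
parameter — no `p(1−p)` relationship is assumed.

The synthetic-data generator (`synthesize_dataset()`) runs the simulator
once, assigns every surviving pair the component mean of its origin event
and draws its similarity from a normal truncated to (0, 1] — truncated, not
clipped, so no mass piles at the bounds. Its ground truth (exact per-event
pair counts, the generating `u` values, the unpaired count) supports
parameter-recovery experiments. What it deliberately does not emulate:
noise pairs unrelated to any event (available as an optional uniform
mixture component at fit time, off by default), similarity-dependent noise
inhomogeneity, assembly/annotation artefacts, and any within-genome
syntenic structure. Passing recovery tests on this generator therefore
shows the inference chain is correct *under the model*, not that real
SynMap tables are free of those complications.

Truncation bias: for a component with sd ≤ 0.05 whose mean is at least two
sds away from both bounds, the truncated mean is within 0.005 of the
nominal mean. A component pressed against a bound is genuinely distorted —
at mean 0.95 with sd 0.05 the truncated mean sits ≈ 0.014 low. The default
sd model keeps high-similarity components clear of that regime.

## Inference

Overlapping components make naive averaging or fully unconstrained mixture
decomposition unreliable, so the package follows a two-stage procedure:

1. **Local modes** (`find_local_modes()`): the sample is binned (default
   bin width 0.01 similarity), smoothed with a centred moving average
   (default 5 bins), and local maxima are scored by topographic prominence
   relative to the global peak (default threshold 5 %). Ties between
   equal-height adjacent bins resolve to the leftmost bin. The defaults
   trade mode precision against spurious-mode proliferation; both effects
   are property-tested. Across related comparisons,
   `shared_mode_alignment()` clusters per-sample modes by single linkage
   (default merge threshold 0.03) and reports median consensus means,
   leaving unmatchable modes unassigned rather than forcing them.
2. **Constrained maximum likelihood** (`fit_constrained_mixture()`): EM for
   a normal mixture with the means *fixed* at the anchors; only sds and
   weights are free. Convergence at log-likelihood gain < 1e-8 or 500
   iterations; component sds are floored at 1e-4 and flagged if they
   collapse. An optional refinement pass lets means move at most one bin;
   it is off by default because fixed anchors are the point of the
   procedure. Per-component pair counts are `weight × n`.

Survival probabilities are then estimated by `estimate_survival()`: the
per-origin counts (plus optionally the unpaired count) are treated as one
multinomial draw whose cell probabilities are the normalised expected
counts of a user-supplied skeleton (ploidies and times fixed, `u` free),
and the likelihood is maximised by quasi-Newton iterations from ten random
starts (the likelihood develops flat ridges when components overlap).
Parameterisation: one `u_2` per event on a logit scale; triplings impose
`u_3 = u_2^2` (the joint survival of two extra copies approximated by the
product of their individual survivals), which also bounds
`u_2 < (√5−1)/2` for feasibility; `u_0 = 0` is imposed by default and can
be released, at the cost of one extra parameter per event. The fit refuses,
with an explicit message, problems with more free parameters than
independent proportions — for a two-WGD paralog schedule the unpaired cell
is what makes the second parameter estimable, and the same holds for
scenarios via the ortholog-unpaired expectation.

Post-speciation WGD survivals are *not* estimable from ortholog
proportions: the amplification product `F_A F_B` multiplies every cell and
cancels under normalisation. They are instead estimated by
`estimate_amplification()`, the slope through the origin of pair counts in
comparisons against the WGD-bearing species on counts against an outgroup —
the regression route the figure-based analysis uses. Rates follow from
`u = e^(−ρΔt)` (`fractionation_rate()`, `rate_estimates()`); the interval
of an event runs from its time to the next event's time, and for the last
shared event of a scenario to the first post-speciation event in either
branch (the first interruption of that fractionation regime), or the
observation when there is none. `rate_consistency_report()` summarises the
spread of `ρ` across comparisons sharing an interval (flag threshold:
coefficient of variation 0.2 by default), since the model presumes a single
rate per interval regardless of which descendant genome is examined.

## Numerical choices

* Extinction probabilities: ploidy 2 uses the closed-form quadratic root
  `min(1, (1−u_1)/u_2 − 1)`; other ploidies a bracketed root search on
  [0, 1) with tolerance 1e-12, after the exact shortcuts `u_0 = 0 → 0` and
  `mu ≤ 1 → 1`. Agreement with fixed-point iteration of the generating
  function is property-tested to 1e-10.
* Probability vectors must sum to 1 within 1e-9 and are renormalised only
  inside that tolerance; anything further off is rejected, not repaired.
* Expectations are computed as O(n) moment products; exhaustive history
  enumeration (the multinomial form) is retained purely as a test oracle,
  and the per-event multinomial includes the `u_0^{a_0}` factor so that
  history probabilities sum to one.
* The simulator draws survivor counts directly from the categorical `u`
  (not by thinning Bernoullis), never materialises dead subtrees, and runs
  replicate batches as one flat forest with vectorised per-generation draws
  and a vectorised backward pass over parent pointers; pair counts by MRCA
  fall out of subtree leaf-count sums, so no pairwise enumeration is needed
  for counting.
* Truncated-normal draws use the inverse-CDF construction, exact for the
  (0, 1] range at the parameter magnitudes used here.

## Problem sizes

The test suite validates the enumeration oracle on schedules with at most
two initial genes and three WGDs, simulator agreement at 1e5 replicates
(3-standard-error acceptance), and full-chain rate recovery (synthesize →
modes → constrained EM → survival ML → ρ) at roughly 2×10^4 pairs per
dataset over ten seeds for two- and three-event schedules, with all rates
recovered within 20 % relative error when components are separated by at
least ~2 sds. Recovery degrades when components merge — a three-event
chronology whose middle component sits 2.2 sds from its neighbour is
already effectively unimodal at these sample sizes, which is a property of
the observation model, not of the optimiser.

## Limitations

* No variances for pair counts are provided (only expectations);
  uncertainty is assessed by simulation.
* The generation-synchronous branching process has no continuous-time
  birth–death interpretation; event times live outside the process.
* Ks/4DTv computation from sequences, synteny validation, and genome-scale
  comparisons are out of scope: the package starts from a gene-pair
  similarity table.
* The cross-comparison mode-alignment procedure is a concrete rendering of
  an inherently narrative constraint ("the same events should surface in
  several comparisons"); its single-linkage threshold is a tunable, not a
  derived quantity.
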