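---
title: "Models of gene-cluster evolution in operonevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of gene-cluster evolution in operonevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(operonevo)
```

Genes contributing to one metabolic pathway are often found clustered on
bacterial chromosomes, frequently as operons. `operonevo` implements three
stochastic models of how such clusters might arise and persist, together
with sensitivity-analysis tooling. This vignette describes the shared
genome representation, each model and its assumptions, the parameters that
matter, the numerical choices made, and what the package's tests do and do
not establish.

## The genome representation

All models share a deliberately abstract representation. A genome is a
circular chromosome of `L` kb (default 4,900) carrying `n` pathway genes
(default 3), each 1 kb long and identified with its integer position; no
two genes may occupy the same position. The clustering statistic is the
**minimum arc distance** `d`: the length of the shortest contiguous arc
containing all pathway genes, equal to `L` minus the largest gap between
neighbouring genes. For `n = 3` genes placed uniformly at random the
largest of the three circular gaps has expectation `(L/3)(1 + 1/2 + 1/3) =
11L/18`, so `E[d] = 7L/18` — about 1,906 kb at the default length. This
closed form anchors several tests and makes the default `L` self-consistent
with a random-initialization mean of roughly 1,900 kb.

Rearrangement is by **translocation** (one gene moves to a uniformly chosen
unoccupied position) or **inversion** (two breakpoints are drawn uniformly
on `{1..L}` and shifted by −0.5 so they fall between genes; every gene at
`g` strictly inside the segment is reflected to `a + b − g`). The
replication origin is fixed at position 0 and the terminus at `L/2`.
An inversion that displaces either landmark by more than a tolerance `T`
(default 100 kb) is lethal — large replichore imbalances are strongly
selected against in real genomes. Because linear segments with `a ≤ b`
never contain the origin, the rule reduces to a three-clause disjunction:
the segment lies entirely on one side of the terminus, or the reflected
terminus `a + b − L/2` moved at most `T` (displacement `|a + b − L|`).

A genome is "clustered" when `d` falls below 3 *minutes*, i.e. `3L/100` kb
(147 kb at the default length), following the classical *E. coli* mapping
unit.

## The selfish-operon species pool

`run_selfish()` follows a pool of *positive* species — species whose
members carry the functional pathway — each monomorphically associated with
one arrangement. Per time step, each species in index order:

1. rearranges with a variant-specific probability (see below);
2. loses the function with probability `P_loss` (default 0.001) and leaves
   the pool;
3. if the pool currently holds fewer than 900 species, recruits a negative
   species (limitless supply) with probability `P(d) = P_max e^{−λ_t d}`,
   the recruit copying the donor's arrangement. Recruits are appended after
   the sweep and not iterated in the step that created them.

`P_max` (default 0.01) applies when the genes share a minute; the decay
`λ_t` defaults to `ln(6)/450` per kb so that a 50 kb fragment is exactly 6
times more likely to transfer than a 500 kb one. The distance bias of
horizontal transfer is the only force favouring clustering — an *indirect*
selection at the species level.

Three rearrangement variants are provided: the original process
(rearrangement always moves a pathway gene), a corrected process in which
the pathway genes are hit only with probability `n/L` (their share of the
genome), and an inversion variant subject to the viability rule, where a
lethal inversion leaves the species unchanged (the species survives the
death of the rearranged individual). The default `ρ = 10⁻⁵` is deliberately
low; the corrected variant lowers the effective rate by a further factor
`n/L` (~6 × 10⁻⁴), reflecting how rarely rearrangement hits a specific
pathway.

Population dynamics at the default rates deserve comment. A species with a
random arrangement (`d ≈ 1900` kb) has a transfer probability of about
5 × 10⁻⁶ — far below `P_loss` — so most founding lineages decay. Only
species with `d` below roughly 580 kb (where `P(d) > P_loss`) found
supercritical lineages; about 4 of the 100 initial species qualify on
average. These lineages grow to the 900 cap while dominating the pool,
which is why the pool mean distance first *dips* (to a few hundred kb)
before cap-regime dynamics set in. Because each founding lineage is a
near-critical branching process, a noticeable minority of runs (roughly a
quarter at the defaults) lose all supercritical founders and the whole pool
goes extinct; such trajectories are truncated and flagged `extinct` rather
than being resampled, since extinction is genuine model behaviour. The
original lower bound of 10 species is reported but not enforced — the
historical intervention at that floor is undocumented, and no intervention
is a defensible, explicit choice.

The species count only reaches, never exceeds, 900: recruitment counts the
recruits already granted during the sweep against the cap, matching the
description of transfer being switched off the moment the pool is full.

The time step of this model is not calibrated to any physical unit, so
trajectories are labelled in "steps".

## The Moran model with inversions

`run_moran()` tracks `N` individual cells. All start with one shared
uniform random arrangement. Per elementary step, one individual is chosen
uniformly and a breakpoint pair drawn; with probability `ρ` an inversion is
attempted (viable: applied in place; lethal: the individual dies and is
replaced by the offspring of a fitness-proportional parent), otherwise the
chosen individual dies and is replaced by the offspring of a
fitness-proportional parent from the whole population. One generation is
`N` steps. Here selection for proximity is *direct*: relative fitness is
`w(d) = e^{−λ d}` (exponential, default `λ = 0.001`/kb) or a steep logistic
`w(d) = 1/(1 + e^{k(d − m)})` with midpoint `m = 12.5` kb and steepness
`k = 0.5`/kb, under which fitness collapses between 5 and 20 kb.

Two readings of the verbal model were genuinely open and are resolved as
explicit choices:

* after a *lethal* inversion the replacement parent is drawn from the
  other `N − 1` individuals (the focal genome is dead); a configuration
  switch (`lethal_excludes_self = FALSE`) restores whole-population
  sampling, and at `N ≥ 20` the two are practically indistinguishable;
* in the no-inversion branch the *chosen* individual is the one that dies,
  which makes the neutral case (`λ = 0`) the textbook Moran process — the
  package tests exploit this by checking that a neutral class fixes with
  probability equal to its initial frequency and a selected class with the
  exact birth–death absorption probability `(1 − r^{−i})/(1 − r^{−N})`.

Fitness values are cached per individual and invalidated when a genome
changes; the cache holds *log* fitness, and sampling weights are formed as
`exp(log w − max log w)`, so the steep sigmoid remains usable at distances
where `w` itself underflows double precision (beyond ~1,400 kb). This is an
exact reformulation, not an approximation.

Moran runs cost `O(N)` per elementary step and `O(N²)` per generation, so
whole-parameter-space exploration is impractical — the motivation for the
substitution model below. Package tests use `N ≤ 60` and a few hundred
generations, which suffices for the fixation-probability and
trajectory-shape checks.

## The rearrangement-substitution model

`run_subst()` compresses time by assuming the population is monomorphic
between substitutions (`Nρ` must be small; the constructor warns above
0.1). The cycle implemented by `subst_event()`:

1. wait a geometric time (parameter `p = 1 − (1 − ρ)^N ≈ Nρ`) for the next
   rearrangement proposal anywhere in the population;
2. draw breakpoints; a non-viable inversion consumes the waiting interval
   and nothing else;
3. otherwise compute `s = w(d_new)/w(d_old) − 1` and accept with the
   diffusion-theory fixation probability
   `π(s) = (1 − e^{−2s})/(1 − e^{−2Ns})`;
4. on acceptance, advance the clock additionally by the conditional mean
   fixation time and replace the resident arrangement.

The run stops once the clock passes `t_end` (default 50,000 generations).
The diploid diffusion results are applied to haploids with `N_e = N/2`,
which gives the neutral limits `π(0) = 1/N` and mean conditional fixation
time `≈ 4N_e = 2N` generations. Expected fixation time is charged only for
*successful* substitutions; excursions of arrangements that are eventually
lost are not separately charged, as their sojourns are brief and the model
is explicitly an origin-fixation approximation.

### Numerical choices

* `π(s)` is evaluated as `expm1(−2s)/expm1(−2Ns)`, exact and stable through
  `s = 0` from both sides; for `2N|s| > 700` (strongly deleterious) a
  log-space branch avoids overflow. The boundary `s = −1` (a proposal whose
  fitness ratio underflows) returns the correct limit 0.
* The conditional fixation time is computed by numerical quadrature of the
  Kimura–Ohta conditional sojourn-time density (the Green-function form),
  written in terms of `expm1` so no intermediate overflows; the neutral
  closed form `−2N(1 − p)ln(1 − p)/p`, `p = 1/N`, is used below
  `|s| < 10⁻¹⁰`. Conditional fixation time is an even function of `s`
  (Maruyama–Kimura symmetry), so deleterious coefficients are folded to
  `|s|`. Above `S = 2N|s| = 10⁶` the integrand's boundary layers defeat
  adaptive quadrature while the true time is already down to a few
  generations, so `S` is capped there; the error is a handful of
  generations against a 50,000-generation horizon. The quadrature was
  validated against a brute-force haploid Wright–Fisher simulation
  (`N = 50`, `s = 0.05`, 2,000 conditional fixations) in the test suite.
* Geometric waiting times are sampled by uniform inversion
  (`⌊ln U / ln(1 − p)⌋ + 1`), which is exact and remains correct for
  `p ~ 10⁻⁸` where integer-typed samplers can overflow.

A caveat surfaced by testing: the diffusion `π(s)` uses the Wright–Fisher
offspring-number variance. The *Moran* process has twice that variance per
generation, so `π(s)` and the exact Moran absorption probability agree only
under weak selection (they diverge towards `2s` vs `s` once `Ns` is large).
The consistency test between the two therefore probes `|Ns| ≤ 0.15`; the
two models are not interchangeable outside that regime, and the
substitution model is calibrated to Wright–Fisher dynamics.

## Sensitivity analysis

`lhs_sample()` builds latin hypercube designs: each parameter's range is
cut into `k` equiprobable strata, exactly one point falls in each stratum,
and strata are permuted independently across parameters (stratification
delegated to `lhs::randomLHS`). Ranges spanning at least two orders of
magnitude are stratified on the log scale by default, since rates such as
`ρ`, `N` and `λ` vary over decades and linear stratification would waste
nearly all points at the top decade; the choice is recorded per parameter
in the design object. `param_sweep()` runs any of the three simulators over
a design or plain grid, with per-replicate seeds derived from a master seed
by a counter scheme (`master_seed + (point − 1)·sims + replicate − 1`), so
sweeps are bit-reproducible and independent of execution order; failed
(extinct) replicates are reported per point, never dropped. Point summaries
are the replicate mean and the central 90% interval (5th–95th percentiles),
the convention used for simulation error bars throughout. `kendall_tau()`
(tau-b, tie-corrected, via `stats::cor.test`) screens the direction and
detectability of each parameter's effect.

Default sweep ranges for the substitution model are `ρ ∈ [10⁻¹⁰, 10⁻⁶]`,
`N ∈ [10², 10⁶]`, `λ ∈ [10⁻⁴, 10⁻¹]` (all log scale) and `n ∈ {3,…,10}`,
bracketing the transitions seen in one-at-a-time sweeps. Across such a
design, final distance falls with `ρ`, `N` and `λ` and rises with `n`. The
`λ` effect is by far the weakest: across most of the box either selection
is already overwhelming at the smallest `λ` (large `N`) or there are no
proposals to select among (small `N·ρ`), so `λ` is only decisive in the
thin slice where selection is marginal (`N·λ·Δd ~ 1`). Its marginal rank
correlation over the joint design is correspondingly close to zero even
though the one-at-a-time `λ` response is strongly monotone (both are
checked in the test suite). The package's sign-reproduction test
therefore replicates the
50-point/10-sim screening experiment over three consecutive master seeds
and reads each parameter's sign from the pooled tau: replication shrinks
Monte Carlo error without biasing the estimate, recovering the subtle `λ`
direction while the three strong effects are unambiguous in any single
replicate.

## What the synthetic setting does and does not show

All inputs are generated by the package itself; there is no empirical
genome data anywhere. The simulators emulate: uniform random initial gene
placement, distance-biased transfer, replichore-imbalance lethality, and
selection on a single scalar statistic (`d`). They deliberately ignore:
real gene lengths and annotation, nucleotide sequences, within-species
polymorphism (selfish and substitution models), clonal interference,
duplication-based gene gain, multi-pathway genomes, and any calibration of
the selfish model's time step to physical time. Consequently, passing
tests establish internal consistency of the models and faithful
implementation of their mathematics — not that any particular mechanism
operates in real bacterial populations.

## Problem sizes used by the test suite

Stochastic assertions use fixed seeds and deliberately modest sizes chosen
to keep the full suite in the minutes range: 10⁴ arrangements for
initialization statistics, 2,000 Moran fixation replicates at `N = 20`,
2,000 Wright–Fisher conditional fixations for the fixation-time oracle,
~5 × 10⁴ viable proposals for the neutral acceptance rate, ten 15,000-step
selfish-pool replicates for the population-dynamics checks, and the LHS
designs described above. Each stochastic tolerance is stated in the test in
units of the corresponding standard error.
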