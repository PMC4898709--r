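---
title: "Counting origins of bioluminescence and detecting exceptional richness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting origins of bioluminescence and detecting exceptional richness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

lumfish implements a comparative pipeline for a question of the form
"how many times did a binary trait arise across a clade, and are the
trait-bearing subclades unusually species-rich for their age?" — here
phrased for bioluminescence in ray-finned fishes. This vignette is the
package's account of the models it fits, the knobs that matter, what the
synthetic data do and do not emulate, and the numerical choices made
where the design was genuinely open.

## The trait model and its reconstruction

Presence/absence of bioluminescence is modelled as a two-state
continuous-time Markov (Mk) chain along a time-calibrated tree, with a
gain rate `q01` and a loss rate `q10` in events per lineage per million
years. The transition kernel has the closed form

$$P_{00}(t) = \frac{q_{10} + q_{01}e^{-(q_{01}+q_{10})t}}{q_{01}+q_{10}},$$

and analogously for the other entries; `transition_matrix()` exposes it
directly. Tip data enter through Felsenstein pruning (`tree_loglik()`),
with missing states contributing a flat partial likelihood, polytomies
handled as hard multifurcations, and per-node rescaling so that trees of
hundreds of tips do not underflow.

`mk_mcmc()` is the fitting function. It integrates over phylogenetic
uncertainty the way BayesTraits-style analyses do: each MCMC iteration
draws one tree uniformly from the posterior sample *jointly* with a
log-scale multiplier proposal on one of the two rates, and the move is
accepted by Metropolis–Hastings on pruning likelihood times prior. This
is a valid sampler on the product space (rates × tree index) with a
uniform prior over the supplied trees. At each retained iteration the
marginal ancestral-state probabilities — down-pass and up-pass partials
combined at every internal node — are computed on the drawn tree, and
per tree the reconstructions are averaged over the iterations at which
that tree was drawn. Trees never drawn after burn-in have no
reconstruction and are simply absent from the cross-tree summaries.

Tunable parameters, with defaults and reasons:

* **Rate priors** — exponential with mean `1/h`, `h` the mean root age
  of the sample (so roughly one event per root-to-tip path a priori);
  configurable to uniform on `(0, 100/h)`. The prior matters whenever
  one rate is weakly informed: a rare-loss trait leaves `q10` almost
  entirely prior-driven, and its posterior will sit near the prior
  scale no matter the truth.
* **Root prior** — uniform `(0.5, 0.5)` by default; stationary
  (`q10, q01)/(q01+q10)`) and fixed options exist. With a trait as rare
  as bioluminescence the data dominate the root state regardless.
* **Proposal width** — 3 on the log-multiplier scale, tuned for
  acceptance rates in the 0.2–0.5 band on the problem sizes the package
  targets; widths near 1 give acceptance above 0.8 and visibly longer
  autocorrelation times.
* **Chain length** — the `mk_mcmc()` defaults (1.01M iterations, 10%
  burn-in, thin 1000) mirror common BayesTraits practice;
  `pipeline_config()` uses 50,000 iterations thinned to 10 because the
  fixture-scale analyses mix in a few thousand iterations and the
  pipeline wants several reconstruction draws per tree in the sample.

## From reconstructions to origin counts

`binarize_asr()` turns averaged marginals into discrete node states at a
cutoff (default 0.5), resolving exact ties to absence so that the count
is conservative about gains. `count_transitions()` scans every edge; a
0→1 edge is an independent origin, a 1→0 edge a loss — reported, never
folded into origins. The headline number is the *modal* per-tree gain
count across the tree sample, always printed next to the minimum (the
"at least N times" reading) and a central 95% interval.
`origin_sensitivity()` re-runs the binarization over cutoffs 0.5–0.95
as a built-in check that the headline is not a threshold artefact.

Each gain is labelled with the light-production mechanism of the
luminous tips it subtends — intrinsic, bacterially mediated, unknown, or
`mixed` when the subtended tips disagree — and with the smallest named
clade of the richness table that contains it; described species per
mechanism are summed over those clades, each clade counted once.

An alternative estimator, `expected_gains_simmap()`, samples full
character histories (ancestral states from their joint conditionals,
then endpoint-conditioned paths per branch by rejection sampling) and
reports the expected number of gains per history. It is a cross-check,
off by default: unlike edge counting it is sensitive to multiple hits
on long branches.

## Clade richness envelopes and rate shifts

Expected clade sizes under a birth–death process with net
diversification `r` and relative extinction `eps` follow the
Magallón–Sanderson crown distribution conditional on both crown lineages
surviving, with `beta = (e^{rt}-1)/(e^{rt}-eps)`:

$$P(N = n \mid t) = (n-1)(1-\beta)^2\beta^{n-2}, \qquad n \ge 2.$$

`richness_interval()` inverts the closed-form CDF
`1 - n\beta^{n-1} + (n-1)\beta^n` for equal-tail quantiles, so envelope
bounds carry no truncation error; the pmf itself is truncated where the
CDF exceeds `1 - 10^{-9}`. A clade is flagged *exceptional* only when
its described species count lies strictly above the upper bound;
`observed == upper` is within, and clades below the lower bound are
reported as depauperate, never as exceptional.

`medusa_fit()` supplies the background rates. Its likelihood combines,
per piece of the tree, the reconstructed-process density of internal
branching times (assembled per edge as `p1(start)/p1(end)` ratios with a
λ factor per branching, which telescopes to the classical Nee form) with
a taxonomic term per terminal of stem age `t_s` carrying `m` described
species, `p_1(t_s)\beta_s^{m-1}`; this reduces to the plain `p1` factor
for resolved tips and to `(1-\beta_s)\beta_s^{m-1}` in the pure-birth
case. Each piece is conditioned on the survival of its basal lineages
(both crown lineages for the root piece, the stem lineage for a shift
piece); for a single piece the objective then agrees with
`ape::birthdeath` exactly, up to the data-independent `(N-1)!` constant
— a correspondence the test suite asserts.

The stepwise search fits a single model, then scans every stem edge: the
candidate subtree is refit while the donor piece is held at its current
maximum-likelihood parameters (a cheap lower bound on the candidate's
improvement), the three best-scoring candidates are refit in full, and
the best is accepted if AICc improves by at least the threshold
(default 4), repeating until nothing qualifies. AICc uses
`k = 2 × pieces + (pieces − 1)` parameters and `n` equal to the node
count of the tree. Relative extinction is optimised within `[0, 0.99]`
from starts at 0, 0.5 and 0.9 — the profile for `eps` is notoriously
flat and can run to the boundary on single realizations, which is a
property of the likelihood, not of the optimiser. Shift placement is
stem-edge only; a shift inherits the full subtree below its edge, and
nested shifts keep their own pieces.

## What the synthetic data emulate — and what they do not

`make_fish_fixture()` builds the study-shaped dataset every end-to-end
test runs on: a 301-tip birth–death tree rescaled to a 150-Ma crown age
(so simulated origins span an Early-Cretaceous-to-recent window), a
binary trait with exactly 27 true gains split 8 intrinsic / 17
bacterial / 2 unknown, a 500-tree sample created by lognormal node-age
jitter (σ = 0.1) on the fixed topology, and a clade richness table drawn
from planted per-clade rates, a few old clades planted at an elevated
rate so exceptional richness exists by construction.

The gain count is pinned by rejection sampling over trait seeds, and a
candidate painting is accepted only when its origins are *individually
identifiable*: no gain edge nested inside another, no two gains on
sibling edges, no losses beneath any gain (every tip below a gain still
luminous), and, for every pair of gains, absent tips outnumbering
present tips under their most recent common ancestor. Each rejected
condition corresponds to a configuration in which a statistically
correct reconstruction merges or splits neighbouring origins, making
the planted count the wrong yardstick; with the rules in place the
fixture's ground truth is also the reconstruction's attractor. Gain and
loss rates are set from the tree itself (`q01` = 27 / total branch
length, `q10 = q01/10`), the rare-loss regime the trait actually shows.

What the fixture does **not** emulate: topology uncertainty in the tree
sample (jitter moves node heights only), sequence-level inference error,
non-uniform taxon sampling, correlated extinction of luminous lineages,
and any real fish taxonomy — clade names are synthetic labels. Passing
the end-to-end tests therefore demonstrates that the pipeline recovers
a known history under clean phylogenetic uncertainty, not that any
empirical count is correct.

## Calibration studies and the problem sizes used

The test suite runs each statistical check at a size chosen to give
stable verdicts in minutes; all sizes are recorded here as the
package's own choices.

* Exactness: pruning and marginals against exhaustive enumeration on
  trees of 4–8 tips (tolerance 1e-12); the transition kernel against a
  generic matrix exponential and Chapman–Kolmogorov (1e-10).
* Prior recovery: with fully missing data, 10,000 retained samples must
  match the exponential rate prior with a Kolmogorov–Smirnov statistic
  below 0.05.
* Coverage: 20 datasets simulated at `q01 = q10 = 0.05`/Ma on 200-tip
  trees of roughly 20-Ma depth — the depth at which the default prior's
  scale `1/h` sits at the generating value, as a credible-interval
  coverage check requires (with a deliberately conflicting prior the
  same check measures prior influence, not calibration). At least 17
  of 20 joint 95% intervals must cover the truth.
* Clade sizes: the crown pmf against 1–2 × 10⁵ forward-simulated
  surviving crown clades at (r, eps) ∈ {(0.1, 0), (0.1, 0.5),
  (0.08, 0.9)}, total-variation distance < 0.02; the high-extinction
  combination uses the larger simulation because its long tail
  dominates the Monte-Carlo error.
* Shift search: ≤ 10% false positives on 50 homogeneous 100-tip
  pure-birth trees; ≥ 80% stem-edge recovery of a planted 10× clade in
  50 replicates.
* End to end: 10 fixture seeds; at least 8 must yield modal gain count
  27 with the 8/17/2 mechanism split.

## Numerical choices and degenerate inputs

Ultrametricity is validated at a relative tolerance of 1e-6 (clock
trees are ultrametric by construction; the check can be disabled for
trees that legitimately are not). Zero-length branches are legal and
produce identity transition kernels. `expm1`/`log1p` forms keep the
birth–death terms accurate for small `rt`, and a piecewise
`log(expm1(x))` avoids overflow past `x ≈ 30`. Exact binarization ties
go to absence. MCC tie-breaks go to the lowest tree index; summarized
clade heights that cross (parent younger than child, possible with
mean heights on discordant topologies) are clamped to zero-length
branches with a warning. The fixture's richness draws use the negative
binomial representation of the crown distribution, capped below by the
number of sampled tips so tables always validate.

## Known limitations

The Mk model here is strictly two-state: no hidden rate classes, no
covarion behaviour, no mechanism-state evolution (mechanism is a
post-hoc annotation of gains, as in the analyses this mirrors). The
tree integration treats the supplied sample as exchangeable and cannot
correct biases in how it was produced. MEDUSA-style searches inherit
the known flatness of the extinction profile and the stepwise nature of
the search — the reported configuration is a good AICc path, not a
global optimum. Losses are counted but the pipeline makes no attempt to
distinguish secondary loss from trait misscoring.
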