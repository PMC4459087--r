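---
title: "Node-age-dependent bias in calibrated divergence dating: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Node-age-dependent bias in calibrated divergence dating: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satclock)
```

## The problem

Fossil-calibrated molecular dating assumes that genetic distance accumulates
proportionally to time. Substitution saturation — back-substitutions and
repeated hits at the same sites — breaks that proportionality in the deeper
parts of a tree. The consequence is not a uniform error but a *placement-
dependent* one: the apparent clock rate implied by a calibration depends on
how saturated the calibration's own depth is, so the direction and size of
the dating bias at any node depend jointly on the node's age and the
calibration's age. `satclock` implements this mechanism three ways — as a
closed-form model, as emergent behaviour of simulated sequences, and as an
end-to-end sensitivity analysis of a dating engine — so the three levels can
be checked against each other.

## The saturation model and its assumptions

`saturation_model(rate, onset, decay, window)` defines expected percent
pairwise distance as a continuous, strictly increasing, piecewise-linear
function of divergence time:

* `rate` (default **1** % distance per MY): the background, unsaturated rate.
* `onset` (**20** MY): divergence time at which saturation begins.
* `decay` (**0.5**) per `window` (**10** MY): the slope in the k-th window
  after onset is `rate * decay^k`.

Two conventions deserve note. First, *the first post-onset window is already
reduced*: the slope on (20, 30] MY is `rate * decay`, not `rate`. The phrase
"a reduction every `w` MY following the onset" could also be read as the
first reduction applying one window later; we adopt the first reading, under
which the 20–30 MY slope is half the background slope, and expose all four
parameters so the other convention is one constructor call away. Second,
distances are expressed in percent (0–100) on the *pairwise* scale throughout
the analytic module; node heights in the dating engine are per-lineage
(pairwise/2) and fitted rates are reported back on the pairwise scale so the
two layers share units. `pct_to_prop()`/`prop_to_pct()` convert.

The map is a bijection on `[0, Inf)` for `decay > 0`, and `invert_distance()`
is its exact inverse (used to map simulated distances back to time).

Single-calibration dating is `estimated_age(t, a) = d(t)/(d(a)/a)`. For a
calibration set, `pooled_rate()` offers through-origin least squares of
distance on age (default; age-squared weighting makes deep calibrations
dominate, which is why "number of constraints matters less than their age"),
and an unweighted mean of apparent rates as the configurable alternative.

The deviation class (`-`, `0`, `+`) uses a relative tolerance of **5%** by
default. No threshold is inherited from elsewhere; 5% is small against the
effect sizes under study (tens to hundreds of percent) yet forgiving of
sampling noise at desk scale. The same tolerance is shared by the
sensitivity summaries.

## The synthetic data generator

`make_reference_chronogram()` is a fixed, rooted, ultrametric 18-taxon
timetree shaped like the aquatic-bird phylogenies used to study this problem:
six flamingo species in two three-species subclades (crown 4.4 MY, youngest
split 0.5 MY), two grebes (crown 9 MY), their joint crown (Mirandornithes,
34 MY), a tropicbird, a penguin–tubenose pair diverging at 62 MY adjacent to
the 65 MY root, and a core-waterbird clade carrying the pelican (29 MY),
anhinga–cormorant (24 MY), sulid (35 MY) and frigatebird (52 MY) calibration
nodes. Anchored ages sit at or slightly above their fossil minima — matching
dating studies in which calibrated posteriors hug the minimum priors — and
uncalibrated ages are interpolated between the anchors, since no truth exists
for them. The shoebill (*Balaeniceps rex*) is included so that the
ten-outgroup rows of the run grid are realizable; the grebes are sister to
the flamingos and are never counted as outgroups.

`default_calibrations()` carries the seven vetted minimum ages (8.7, 23.0,
28.3, 32.6, 33.0, 51.8, 60.5 MY) with the anhinga constraint (23.0) flagged
optional: the reference analysis uses the other six, and one grid run adds
the seventh. Clades are defined by taxon sets and resolved by MRCA, so they
survive tip pruning and re-rooting. The default prior shape is lognormal with
SD = 1 on the log scale of the offset past the minimum, located so that the
95% quantile of the offset is ~12.5 MY — a soft maximum 10–15 MY past the
minimum when no hard maximum is defensible.

`simulate_alignment()` has two regimes:

* **mechanistic** — finite-state nucleotide evolution (Kimura two-parameter,
  via `phangorn::simSeq`) under a strict clock, with per-branch expected
  substitutions `relative_rate * base_rate/100 * duration`. Saturation is
  *emergent*: observed p-distances bend toward the stationary mismatch
  probability (3/4 at equal base frequencies) with depth. The closed form
  `expected_p_distance()` is the independent oracle. Defaults: nuclear loci
  1000 bp at a per-lineage base rate of 0.1 %/MY (0.2 %/MY pairwise — slow,
  nearly clock-linear over 62 MY), mtDNA 1500 bp at 5x that rate (visibly
  saturated at depth). The 5x ratio and the lengths are choices of
  convenience — large enough that binomial noise does not mask the bias at
  desk scale — and both are arguments, not constants. A simple reversible
  substitution model suffices here because saturation behaviour, not model
  realism, is the object of study.
* **stylized** — pairwise distances drawn directly from a `saturation_model`
  evaluated at each pair's split time, plus binomial sampling noise at the
  locus length (`Inf` gives the exact expectation). This regime makes the
  analytic predictions testable end-to-end with zero simulation variance.

What the generator does *not* emulate: rate variation across lineages or
sites, incomplete lineage sorting and gene-tree discordance, indels and
alignment error, base-composition heterogeneity, and any fossil-record
incompleteness process. Tests passing on these data therefore demonstrate the
saturation mechanism in isolation, not the full error budget of real data.

## The dating engine

`date_tree()` is a deliberately transparent proxy for Bayesian node dating in
the regime where posteriors sit at the calibration minima:

1. **Heights.** Each internal node's height is the mean pairwise percent
   distance between tips in different child subtrees, halved. Distances are
   *uncorrected* p-distances by default: the working hypothesis is precisely
   that model corrections do not fully remove homoplasy, and the stylized
   pipeline treats residual saturation as uncorrectable. A Jukes–Cantor
   correction is available (`correction = "JC69"`) but off by default.
2. **Clamping.** Heights are made monotone root-to-tip by capping a child at
   its parent's height (ties resolve to the parent value); clamped nodes are
   flagged in the output rather than silently adjusted.
3. **Rate.** One strict-clock rate against the calibration minima, in three
   modes. `point_min` (default): through-origin least squares of heights on
   minima — the direct "posterior equals minimum" proxy. `hard_min`: the
   largest rate under which no calibrated implied age falls below its
   minimum, i.e. the binding calibration pins the clock; this mirrors the
   hard lower bound a minimum-age prior imposes in Bayesian samplers, and is
   the mode used for fossil-consistency experiments — under least squares the
   unsaturated young calibrations pull the compromise rate up and even a
   fully calibrated analysis would spuriously reject the oldest fossils.
   `soft`: maximize the product of prior densities (lognormal/normal/uniform)
   of the implied ages, for experiments that widen or reshape priors. In
   `point_min` mode, widening a uniform prior's maximum changes nothing, as
   it should.
4. **Intervals.** Nonparametric bootstrap over alignment columns, resampled
   independently within each locus, with distances, heights and the rate
   recomputed per replicate; 100 replicates by default; percentile 95%
   intervals; `relative_ci` is the interval width over the point age in
   percent. With `bootstrap_reps = 0` the intervals collapse to the point
   estimate.

Multi-locus data are combined by a length-weighted average of per-locus
distance matrices (concatenation-equivalent) by default; per-locus dating
with weighted post-hoc averaging of ages is available (`combine =
"average"`).

`check_fossil_consistency()` reports nodes whose interval upper bound falls
below the minimum age of an attached fossil — held-out fossils included. The
comparison is strict beyond a 1e-9 relative tolerance, so a binding
calibration sitting exactly at its minimum is not a "rejection".

## The sensitivity harness

`make_run_grid()` encodes 45 comparative runs around the reference analysis
(run 3: seven nuclear loci, eight outgroups, six constraints), varying one
factor at a time: adding/removing mtDNA, subsets of 4–6 loci (alphabetical,
deterministic), leave-one-locus-out, outgroup pools of 10/9/8/3 taxa (a fixed
inclusion-priority list), flamingo subsampling (one species per subclade,
alphabetical), grebe exclusion (which also removes the two constraints whose
clades then become unresolvable), young-only/oldest-only/single/added
constraint schemes, an exploratory 5.33 MY crown-flamingo constraint that
deliberately exceeds the fixture truth of 4.4 MY, and prior-shape variants.
Runs probing machinery a distance engine does not possess are retained but
flagged `approximate`: the two zero-constraint "joint prior" runs cannot be
dated by a calibrated clock and are skipped with a message; the
"unpartitioned" run maps to the engine's default pooled-distance combination;
the prior-shape runs use `soft` mode.

`run_sweep()` dates every run on its own pruned tree and matches nodes across
runs by the MRCA of the shared taxa, reporting percent deviations from the
reference run. `summarize_table2()` compares each run against the baseline
that isolates its factor (reduced-outgroup runs against their full-outgroup
counterparts, not against the reference), and reports the maximum-magnitude
deviation and sign class for a representative young node (crown flamingos)
and old node (penguin–tubenose split).

## What the package reproduces, and what it does not

On its default synthetic data the package reproduces, and its tests assert,
the directional findings: an unsaturated calibration dates all unsaturated
nodes exactly and truncates deep ones; saturated calibrations inflate young
nodes, the more so the deeper the calibration; young-only calibration
produces ages rejected by the deep fossil record while full calibration does
not; adding a fast mitochondrial locus under deep calibration inflates young
nodes (averaged over simulation seeds) while leaving the deep calibrated node
in place; and outgroup count has no effect. Published magnitudes of such
deviations (hundreds of percent on real alignments under full Bayesian
machinery) are *not* reproduction targets — only signs and orderings are.

Known limitations:

* The underestimation of a young crown node under sparser ingroup sampling
  reported from Bayesian/coalescent analyses is *not* reproduced: a mean
  cross-subclade distance is unchanged in expectation by subsampling one tip
  per subclade, so the distance proxy has no mechanism for it.
* `soft` mode approximates individual priors only; the joint-prior
  interactions of a Bayesian sampler (where one prior reshapes another
  through the tree prior) have no analogue here, and no claim is made of
  matching prior-shape effect sizes.
* No relaxed clocks, no topology inference, no convergence diagnostics —
  precision is summarised by the bootstrap `relative_ci` instead of ESS.

## Numerical choices and problem sizes

Degenerate inputs are defined: zero substitution rate yields identical
sequences; identical sequences yield zero heights and zero ages; an empty
fossil table yields an empty violation list; `bootstrap_reps = 0` yields
degenerate intervals. All stochastic steps take explicit seeds and equal
seeds give byte-identical outputs.

The test suite exercises the pipeline at deliberately small sizes: 8-taxon
trees with two 1000-bp loci and 100 bootstrap replicates for the coverage
experiment (20 seeds; truth is required inside the 95% interval for at least
90% of node-seed combinations), exact stylized distances for the
fossil-consistency and sweep direction checks, and 8 seeds of full
mechanistic simulation for the mitochondrial direction check. These sizes
were chosen so the documented effects dominate sampling noise while the whole
suite runs in well under a minute per module.
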