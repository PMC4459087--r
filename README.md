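# satclock

Substitution saturation biases fossil-calibrated molecular divergence dating
in a way that depends on *where in the tree the calibrations sit*. When
repeated substitutions at the same sites (homoplasy) erode genetic distance
in the deeper parts of a phylogeny, a strict-clock rate inferred from a deep
fossil calibration is an underestimate of the true background rate — so young
nodes come out too old. Conversely, a rate anchored only on shallow,
unsaturated calibrations is (correctly) fast, and deeply saturated nodes come
out far too young — young enough to be rejected by the very fossil record the
clades demonstrably possess.

`satclock` packages this mechanism end-to-end for people who study
calibration strategy in molecular dating (and for anyone dating a recent
radiation with external calibrations): a closed-form saturation model, a
synthetic multi-locus data generator over an aquatic-bird-like reference
timetree, a distance-based strict-clock dating engine with minimum-age fossil
calibrations and bootstrap confidence intervals, and a sensitivity harness
that sweeps calibration, locus and taxon sampling schemes.

## The model

Expected percent genetic distance between two lineages separated for `t` MY
is piecewise linear:

    d(t) = r·t                                   for t ≤ T0
    d(t) = r·T0 + Σ_{k=1..K} r·f^k·(time in window k)   for t > T0

with background rate `r` (default 1% per MY), saturation onset `T0` (20 MY),
and the slope multiplied by `f` (0.5) in each successive window of `w`
(10 MY) after the onset — i.e. a 50% rate reduction every 10 MY past 20 MY.
A fossil calibration at true age `a` implies the apparent clock rate
`d(a)/a`, so a node of true age `t` is estimated at

    t̂ = d(t) · a / d(a)

which equals `t` exactly whenever both `t ≤ T0` and `a ≤ T0`, exceeds `t`
when the calibration is saturated and the node is not, and falls below `t`
for sufficiently deep nodes under any calibration. Several calibrations are
pooled by through-origin least squares of distance on age (the rate
`Σ aᵢdᵢ / Σ aᵢ²`), by an unweighted mean of apparent rates, or — mirroring the
hard lower bound a minimum-age prior imposes in Bayesian dating — by the
largest rate under which no calibrated node falls below its minimum
(`hard_min`).

The dating engine applies the same logic to data: node heights are mean
between-subtree p-distances halved, one clock rate is fitted against the
fossil minima, ages are heights over rate, and confidence intervals come from
a nonparametric bootstrap over alignment columns within each locus.

## Worked example

```r
library(satclock)

m <- saturation_model()          # 1 %/MY, onset 20 MY, 50% decay per 10 MY
bias_profile(m, true_ages = c(5, 10, 40, 62), cal_age = 60)
#> # A tibble: 4 × 4
#>   true_age estimated_age deviation_pct class
#>      <dbl>         <dbl>         <dbl> <fct>
#> 1        5          10.2        104.   +
#> 2       10          20.4        104.   +
#> 3       40          56.2         40.4  +
#> 4       62          60.1         -3.02 0
```

A single 60-MY calibration (deep in the saturation zone) roughly *doubles*
the age of every unsaturated young node while dating nodes near its own depth
about right — the `+`/`0`/`-` classes mark over-, correct and under-estimation
at a 5% relative tolerance.

The same pattern emerges from "data". Below, exact saturated distances over
the 18-taxon reference chronogram are dated with only the two youngest
fossil constraints (crown grebes 8.7 MY, crown Mirandornithes 32.6 MY), and
the result is checked against all seven vetted fossil minima:

```r
tr <- make_reference_chronogram()
d  <- stylized_distances(tr)                       # % distances, saturated
cals  <- default_calibrations()                    # six reference constraints
young <- cals[cals$clade %in% c("crown_Podicipedidae", "crown_Mirandornithes"), ]

dt <- date_tree(tr, d, young, mode = "hard_min", bootstrap_reps = 0)
check_fossil_consistency(dt, default_calibrations(include_anhinga = TRUE))
#> # A tibble: 3 × 4
#>   clade             min_age point_age ci_high
#>   <chr>               <dbl>     <dbl>   <dbl>
#> 1 stem_Sulidae         33        32.9    32.9
#> 2 stem_Fregatidae      51.8      36.2    36.2
#> 3 stem_Spheniscidae    60.5      36.9    36.9
```

Young-only calibration dates the sulid, frigatebird and penguin stem nodes
(true ages 35, 52 and 62 MY) at 33–37 MY — all three rejected by their fossil
minima. Re-dating with all six constraints (`date_tree(tr, d, cals,
mode = "hard_min", ...)`) removes every violation. The full sensitivity
design is in `make_run_grid()` (45 runs) and executed by `run_sweep()`;
`summarize_table2()` and `scatter_pairs()` condense the sweep to per-factor
deviation classes and a young-vs-old node scatter.

A command-line wrapper (`inst/cli/satclock`) exposes the pipeline as
`simulate`, `date`, `sweep`, `bias-profile` and `report` subcommands; all
take `--seed`, and `date` writes a `dated.nwk` whose node labels carry the
estimated ages as `age=<MY>` comments with branch lengths in MY.

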