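# gritclean

Behavioral-economics tools for food cleaning in primates. Monkeys that
receive provisioned food on sandy beaches — like the long-tailed macaques
of Koram Island, Thailand — either brush sand off by hand or carry food
to the ocean and wash it. Both behaviors face diminishing returns, and
`gritclean` asks the marginal-value-theorem question: *how long should a
rate-maximizing forager clean, and how far do real monkeys overshoot?*

The package is for behavioral ecologists working with cleaning-efficacy
assays, food-handling bout data and food-surface particle samples.

## The model

The fraction of sand removed after `t` seconds of cleaning saturates as

    g(t) = t / (c + t)

where `c` (s) is the *cleaning inefficiency* — the half-saturation
constant. With a handling time `h` (a 1 s assessment period plus, for
washing, the walk to the water), the removal rate per unit of total time,

    R(t) = g(t) / (h + t),

peaks at the optimal cleaning time

    t* = sqrt(c * h),     R(t*) = 1 / (sqrt(c) + sqrt(h))^2.

`gritclean` estimates `c` from assays by inverting `g` (`c = t(1-g)/g`),
propagates uncertainty by Monte Carlo, maps the equal-rate frontier
`sqrt(c) + sqrt(h) = const` separating wash-worthy from brush-worthy
conditions, computes overcleaning factors from bout data, summarizes
sand-particle morphometrics (circularity `4πA/P²`, caliper Feret
diameters, the 25 µm grittiness fraction), and ships seeded synthetic
generators plus a parameter-recovery harness so the entire pipeline is
testable without field data.

## Worked example

Fit the model to the field efficacy assays (about 3 s of brushing removes
75% of grit; about 3.5 s of washing removes 93%):

```r
library(gritclean)

assays <- data.frame(
  behavior            = c("brushing", "washing"),
  time_s              = c(2.97, 3.53),
  removal_fraction    = c(0.75, 0.93),
  removal_fraction_sd = c(0.07, 0.04))

fit <- cleaning_model(assays, seed = 1)
fit
#> Optimal cleaning-time model (saturating removal kinetics)
#>   brushing  c = 0.99 +/- 0.38 s, h = 1.00 s, t* = 0.98 +/- 0.20 s
#>   washing   c = 0.27 +/- 0.15 s, h = 23.00 s, t* = 2.57 +/- 0.94 s
```

Brushing is intrinsically sloppy (`c = 0.99` s) but cheap (`h = 1` s);
washing is efficient (`c = 0.27` s) but costs a 22 s walk. The predicted
optima: brush for ~1 s, wash for ~2.5 s.

```r
predict(fit)
#>   behavior t_star_point mc_mean mc_sd ci_lo ci_hi
#> 1 brushing        0.995   0.976 0.204 0.607  1.27
#> 2  washing        2.472   2.574 0.938 1.114  4.21
```

Observed high-sand cleaning durations (~3.1 s brushing, ~3.3 s washing)
against these predictions give the overcleaning factors:

```r
overcleaning_factor(3.1, fit$optima$brushing)  # 3.18
overcleaning_factor(3.3, fit$optima$washing)   # 1.28
```

Both exceed 1 — the monkeys clean past the point of diminishing returns —
and brushing is overshot far more than washing.

End-to-end on synthetic data (bout filtering, treatment summaries,
model-ready export, morphometrics):

```r
run_full_analysis(pipeline_config(out_dir = "out", seed = 1))
```

See `vignette("cleaning-economics")` for the model's assumptions,
samplers, generator design and limitations.

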