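# gencycles

Detection and analysis of **generation cycles** — population oscillations
with a period of roughly one generation, driven by synchronised age
structure rather than seasonality or natural enemies — in weekly census
time series from replicated insect mesocosm experiments, with the pyralid
moth *Plodia interpunctella* as the motivating system. Warming experiments
on such populations ask whether temperature and diet quality change mean
density, larval age structure, and the presence of the six-week cycles the
species normally shows; `gencycles` provides the full analysis chain those
questions need, for population ecologists running (or simulating) factorial
mesocosm designs.

## What it computes

**Spectral route.** Weekly dead-adult counts are square-root transformed and
summarised by the raw periodogram
I(f_j) = |Σ_t y_t e^(−2πi f_j t)|²/n on the Fourier grid f_j = j/n.
Significance comes from a Monte-Carlo null: 10,000 negative-binomial
white-noise series with mean and shape matched to the data by moments
(k = m²/(s²−m)), passed through the identical transform path; the
per-frequency 95th quantile is the threshold. A generation cycle is called
when the spectrum beats the threshold at a period of 5–7 weeks.

**Wavelet route.** Loess detrending (span 0.4) removes slow multigeneration
fluctuations, then a Morlet continuous wavelet transform (ω₀ = 6,
Torrence–Compo conventions, e-folding cone of influence) localises
periodicity in time, with pointwise white-noise significance contours and a
ridge-coverage summary.

**Treatment statistics.** Factorial linear models with backward
simplification to a minimal adequate model (sequential sums of squares,
marginality respected) for quantitative measures; an exact r × c
contingency test (full enumeration, multivariate hypergeometric,
probability-ordering two-sided rule) for the qualitative cycling pattern.

**Simulator.** A daily stochastic boxcar model of the moth life cycle with
asymmetric larval competition — late instars cannibalise eggs and early
instars, all larvae compete for food — plus the rotating-section observation
model (full dead-adult census, 1/9-subsampled larval counts, instars 3–5
only). Presets encode a 3-temperature × 2-diet factorial founded with 100
larvae and censused weekly for 82 weeks (62 for larvae).

## Worked example

Simulate the full factorial study, drop the 10-week founding transient, and
summarise each population:

```r
library(gencycles)
study <- generate_study(seed = 1, weeks = 82, larval_weeks = 62)
trunc <- truncate_transients(study, n_drop = 10)
population_summary(trunc)
```

```
   temperature_C     diet replicate mean_adults cv_adults    p5 extinct
1             27     poor         1     10.5833      1.24 0.353   FALSE
4             27 standard         1     21.1667      1.22 0.336   FALSE
10            30 standard         1     26.0417      1.36 0.323   FALSE
17            33 standard         2      0.0000        NA    NA    TRUE
...
```

(18 rows; shown abridged.) The 27/30 °C populations persist with strong
boom-bust dynamics; 30 °C runs carry more adults than 27 °C ones and a
smaller 5th-instar share; the stressed 33 °C populations collapse within a
few generations.

Classify cycles per population and test a cycling-by-treatment pattern. The
canonical outcome for such an experiment — three treatments cycling in all
three replicates, one treatment in none — gives:

```r
calls <- classify_study(trunc, reps = 10000, seed = 1)
cycling_pattern(calls)       # r x 2 table of replicates cycling / not

fisher_exact(rbind(c(3, 0), c(3, 0), c(3, 0), c(0, 3)))
#> Exact contingency test ( full enumeration ): p = 0.01818
```

The exact test enumerated all 20 tables with those margins; the observed
table has null probability 0.00455 and only the four most extreme
arrangements count toward the two-sided p-value of 0.0182.

Wavelet view of one population:

```r
x <- total_adults(trunc)
x27 <- x$adults_total[x$temperature_C == 27 & x$diet == "standard" & x$replicate == 1]
ws <- wavelet_analysis(x27, nsim = 1000, seed = 2)
summarize_ridge(ws)   # fraction of the series with a significant ~6-week period
autoplot(ws)          # heat map with cone of influence and 5% contours
```

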