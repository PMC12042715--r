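# lcgate

Learning-curve analysis for attempt-level surgical-simulation records, with
a Poisson dispersion gate that flags when residual errors have become
random — an operational "efficient skill threshold".

## What it does, for whom

Microsurgical (and other simulation-based) training programmes record, for
every practice attempt, a mistake score and a task completion time (TCT).
An attempt whose total mistake score reaches 5 points (one critical error,
or an equivalent accumulation) counts as a **major-mistake attempt**.
`lcgate` is for surgical educators and skill-assessment researchers who
want to turn such attempt logs into an objective learning curve and an
objective stopping signal.

The headline index is the cumulative **major mistake average**

```
MMA(n) = (# major-mistake attempts among attempts 1..n) / n ,
```

plotted against the number of attempts (NOA). The curve is segmented into
learning periods; each period reports its attempt count, MMA endpoints,
absolute drop and drop rate (drop / NOA). To decide when skill has
plateaued, major-mistake counts in blocks of consecutive attempts are
tested for Poisson conformity with the index of dispersion

```
D = (n - 1) s² / x̄   ~   χ²(n - 1)   under the Poisson null,
```

one-sided against overdispersion. A *positive* verdict (D below the
critical value, e.g. 3.841 at df = 1, α = 0.05) means the remaining
mistakes are statistically indistinguishable from a random process: the
operator has crossed the efficient skill threshold. The package also ships
a three-phase Bernoulli-hazard simulator (unstable phase, exponentially
decaying learning phase, plateau) for calibration, power and
parameter-recovery studies, and a maximum-likelihood fitter for that
hazard model.

## Worked example

```r
library(lcgate)
rec <- simulate_attempts(sim_config(seed = 1))   # a 132-attempt trial
an  <- analyze_attempts(rec)
print(an)
```

```
Learning-curve analysis: 132 attempts, 8 major mistake(s), final MMA 0.061

Learning-curve periods
 period start end noa mma_start mma_end absolute_drop drop_rate n_major
      1     1   5   5     0.000   0.200        -0.200   -0.0400       1
      2     6  12   7     0.200   0.333        -0.133   -0.0190       3
      3    13  19   7     0.333   0.263         0.070    0.0100       1
      4    20  36  17     0.263   0.167         0.096    0.0057       1
      5    37  85  49     0.167   0.082         0.084    0.0017       1
      6    86 132  47     0.082   0.061         0.022    0.0005       1
 tct_average
     2405.25
     2065.25
     1934.50
     1818.56
     1461.46
     1221.15

TCT Linear trend: y = 2028 + -7.772 x, R^2 = 0.358
MMA Exponential trend: y = 0.292 * exp(-0.01347 x), R^2 = 0.876

Poisson gate (dispersion test, block size 4, alpha = 0.05)
 period start end lambda_per_attempt statistic df critical    verdict
      1     1   5            0.20000        NA NA       NA untestable
      2     6  12            0.42857        NA NA       NA untestable
      3    13  19            0.14286        NA NA       NA untestable
      4    20  36            0.05882         3  3    7.815   positive
      5    37  85            0.02041        11 11   19.675   positive
      6    86 132            0.02128        10 10   18.307   positive
Plateau (efficient skill threshold) reached in period 4 (attempts 20-36).
```

Reading it: the MMA rises while early performance is unstable (periods
1–3, drop rates negative or volatile), peaks at attempt 19 (0.263), then
falls — period 4 drops the curve by 0.096 over 17 attempts (rate 0.0057).
The short early periods are too short to bin into enough count blocks, so
the gate reports them as untestable rather than guessing. The first
Poisson-positive period is the detected plateau. Exponential decay fits
the MMA curve far better than a straight line fits the noisy TCT series
(R² 0.876 vs 0.358) — the pattern that makes MMA the more reliable skill
index.

A bundled 18-attempt raw-data sample
(`system.file("extdata", "anastomosis_sample.csv", package = "lcgate")`)
shows the input schema, including absent cells (`-`) and untimed
major-mistake attempts.

### Command line

```sh
exec/lcgate simulate --seed 3 --out attempts.csv
exec/lcgate analyze --input attempts.csv --breakpoints 5,12,19,36,85 \
    --alpha 0.05 --block-size 4 --test dispersion --out out/
exec/lcgate power --reps 500 --seed 2 --out oc.csv
```

`analyze` writes `report.json`, `periods.csv` and `mma.csv`. Exit codes:
0 success, 2 input/schema error, 3 statistical preconditions unmet.

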