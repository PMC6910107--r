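# motorsync

Time-domain motor unit synchronization analysis in R.

Motor units that share excitatory synaptic input tend to discharge
near-simultaneously (within 1–5 ms) more often than chance. `motorsync`
quantifies this from the discharge times of two concurrently active
units: it computes signed **recurrence intervals** from each discharge of
the reference unit (the one with fewer discharges) to the *k*-th nearest
preceding/following discharge of the event unit, bins them into a
**cross-correlation histogram** (1 ms bins, ±100 ms analysis window,
chance level estimated from the ±(60–100) ms baseline bins), locates the
central peak by three methods from the motor-control literature —
investigator-supplied boundaries read off the normalized cumulative sum,
the algorithmic 10–90% cumulative-sum method, and a shuffled-null
z-score threshold (mean + 1.96 population SDs of a surrogate histogram
that redistributes the same intervals uniformly over ± the slower unit's
mean ISI) — and derives six indices from the extra counts *X* above
chance in the peak:

    CIS = X / trial duration          k' = total/expected    k'-1 = X/expected
    E   = X / N_ref                   S  = X/(N_ref+N_evt)   SI   = X/(window counts/2)

plus the peak's z-score significance, duration and center. A paired
renewal-process simulator with injected common-input discharges provides
ground truth for validation.

The package is tidyverse-native: discharge data is an event tibble
(`time`, `unit`), every step returns a tibble or a tidy-able object,
results have `tidy()`/`glance()` methods and ggplot2 `autoplot()`.

## Worked example

Recurrence intervals for the classic six-point worked example — two
units, the second (fewer discharges in the full recording) forced as
reference:

```r
library(motorsync)

ev <- as_event_tbl(data.frame(
  time = c(0.035, 0.115, 0.183, 0.250, 0.306, 0.377,
           0.100, 0.205, 0.298, 0.377, 0.471, 0.577),
  unit = rep(c("motor_unit_1", "motor_unit_2"), each = 6)))

recurrence_intervals(ev, reference = "motor_unit_2") |> head(4)
#> # A tibble: 4 × 4
#>   order reference_time side     interval
#>   <int>          <dbl> <chr>       <dbl>
#> 1     1          0.1   backward   -0.065
#> 2     1          0.1   forward     0.015
#> 3     1          0.205 backward   -0.022
#> 4     1          0.205 forward     0.045
```

Each reference discharge contributes a backward (negative) and a forward
latency to the nearest event-unit discharges: the first reference
discharge at 0.100 s is preceded by an event discharge at 0.035 s
(−0.065 s) and followed by one at 0.115 s (+0.015 s).

A full analysis of a simulated pair with 2 injected synchronous
events/s:

```r
pair <- simulate_pair(duration = 60, synch_rate = 2, seed = 1)
fit <- synch_pair(pair$events, methods = c("cumsum", "zscore"), seed = 1)
fit
#> <synch_analysis> reference 'unit_b' (600 discharges, mean ISI 0.100 s) vs event 'unit_a' (859, 0.070 s)
#>   1199 intervals (order <= 1), binwidth 0.001 s, trial 59.9 s
#> # A tibble: 2 × 7
#>   method   cis k_prime e_index    si peak_duration_s peak_center_s
#>   <chr>  <dbl>   <dbl>   <dbl> <dbl>           <dbl>         <dbl>
#> 1 cumsum 10.7     4.03   1.07  1.10            0.098        -0.001
#> 2 zscore  1.56    2.30   0.156 0.160           0.007         0
```

The z-score method recovers the injected synchrony (CIS 1.56
impulses/s against a 2/s injection with 1 ms jitter; 7 significant
bins centered at zero lag). The cumsum row illustrates a documented
failure mode for very regular trains: with mean ISIs of 70–100 ms and
ISI CV 0.15, first-order intervals cannot reach the ±(60–100) ms
baseline bins, the correlogram is a plateau rather than flat, and the
10–90% boundaries engulf the whole mound (98 ms "peak", inflated CIS).
See the methods vignette (`vignettes/synchronization-methods.Rmd`) for
the analysis and practical guidance; `plot_cumsum(fit$correlogram)` and
`autoplot(fit, method = "zscore")` show the diagnostics.

`tidy(fit)` returns the full per-method index table (including S, k′−1,
peak significance, fallback flags and the recorded seed);
`glance(fit)` summarizes roles, counts, mean ISIs, baseline statistics
and trial duration. `write_synch_report(fit, "report.json")` writes a
schema-versioned, byte-reproducible JSON report.

## Data formats

* **Event list** (`read_event_list()` / `write_event_list()`): CSV/TSV
  with header columns `time` (seconds) and `unit`; delimiter sniffed.
* **Indicator table** (`read_indicator_table()`): a `Time` column plus
  one 0/1 column per unit sampled on a regular grid (e.g. 1 kHz).
* `simulate_pair()` + `write_synthetic_pair()` emit an event list, the
  ground-truth synchronous event times, and a config echo with the seed.
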