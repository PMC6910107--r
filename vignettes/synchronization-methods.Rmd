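---
title: "Time-domain motor unit synchronization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-domain motor unit synchronization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(motorsync)
```

## The problem

Motor units — a motor neuron plus the muscle fibers it innervates — tend
to discharge near-simultaneously (within a few milliseconds) more often
than chance when they share excitatory synaptic input. The strength of
this *short-term synchronization* is estimated from the cross-correlation
of two concurrently recorded discharge trains: the unit with fewer
discharges anchors the correlation (the **reference** unit), and for each
of its discharges we measure the signed latency to the *k*-th nearest
preceding and following discharge of the other (**event**) unit. These
**recurrence intervals** are binned into a cross-correlation histogram
(correlogram); a central peak marks synchronized firing, and indices
computed from the peak quantify its strength.

`motorsync` implements this pipeline end to end: readers for event-list
and sampled indicator-table formats, recurrence intervals at any order,
the correlogram with its baseline statistics, three peak-detection
methods, six synchronization indices, and a controllable simulator for
validation.

```{r pipeline}
pair <- simulate_pair(duration = 60, synch_rate = 2, seed = 1)
fit <- synch_pair(pair$events, methods = c("cumsum", "zscore"), seed = 1)
tidy(fit)[, 1:7]
```

## The model and its conventions

**Roles.** The unit with fewer discharges is the reference; ties go to
the unit appearing first. A forced assignment is available via
`reference =` for reproducing published analyses.

**Recurrence intervals.** For reference discharge time $t$ and order $k$,
the backward interval is the latency to the $k$-th nearest event
discharge strictly before $t$ (negative) and the forward interval to the
$k$-th nearest at or after $t$. An event discharge exactly at $t$ counts
once, as a forward interval of 0: a single physical coincidence must not
be double-counted on both sides. Discharges near the edges of the event
train simply lack the missing neighbour. First-order intervals are the
default; higher orders can be pooled, but harmonics of regular firing can
then produce non-physiological peaks at long latencies.

**Binning.** Intervals are discretized into contiguous half-open bins
$[\ell, \ell + w)$ with 0 as a bin left edge, default $w = 1$ ms — the
resolution needed to resolve short-term synchronization. Bin labels are
left edges. The analysis window is the bins with left edge in
$[-100, +100]$ ms (201 bins at 1 ms); the **baseline region** is the bins
wholly within $\pm(60\text{–}100)$ ms (80 bins), whose mean and
*population* SD estimate chance-level counts. Histograms are zero-padded
to cover the window; intervals beyond it stay in the histogram but are
excluded from the analysis.

**Normalized cumulative sum.** Baseline-mean-subtracted counts are summed
progressively across the window and divided by the baseline mean. A
synchronization peak appears as a steep positive deflection near lag 0.

## Peak detection

Three methods return the same `peak_region` contract (bins, threshold,
significance, provenance):

* **visual** (`peak_manual()`): the investigator reads the boundaries off
  the cumulative-sum plot and supplies them; bins whose left edge lies in
  `[left, right)` form the peak. The workflow is deliberately
  non-interactive — inspect `plot_cumsum()`, then rerun with
  `boundaries =` — so analyses stay scriptable and auditable.
* **cumsum** (`peak_cumsum()`): boundaries are the first bins at which
  the cumulative sum reaches 10% and 90% of its range (minimum to
  maximum); the run between them is the peak. It is significant if its
  mean count exceeds the baseline mean + 1.96 baseline SDs; otherwise
  the method falls back to the default ±5 ms region (bins wholly within
  ±5 ms, 10 bins at 1 ms) with `significant = FALSE`. A zero-range
  cumulative sum, or a 90% crossing preceding the 10% crossing, also
  falls back.
* **zscore** (`peak_zscore()`): a surrogate "shuffled" histogram redraws
  the same number of intervals uniformly over ± the mean ISI of the
  slower unit and bins them identically; the significance threshold is
  the shuffled counts' mean plus 1.96 population SDs. Experimental bins
  within ±10 ms of zero lag are tested individually; those above
  threshold form the (possibly non-contiguous) peak. With no bin above
  threshold, every index is returned as 0. One shuffled realization is
  drawn per analysis, so the seed is mandatory and recorded.

Where the field's descriptions are silent we fixed conventions
explicitly: peak duration is the number of peak bins times the bin width;
the peak center is the left edge of the middle peak bin (lower-middle for
an even run; the median significant bin for zscore). These are declared
conventions, not recovered from any other implementation.

## Synchronization indices

With $T$ = total counts in the peak, $E[C]$ = expected counts (per-bin
chance count × number of peak bins) and $X = \max(0, T - E[C])$ the
extra counts:

$$\mathrm{CIS} = X / \text{trial duration}, \quad
k' = T / E[C], \quad k' - 1 = X / E[C],$$
$$\mathrm{E} = X / N_\mathrm{ref}, \quad
\mathrm{S} = X / (N_\mathrm{ref} + N_\mathrm{evt}), \quad
\mathrm{SI} = X / (\text{window counts} / 2).$$

The per-bin chance count is the baseline mean for the visual and cumsum
methods and the shuffled-null threshold for the zscore method, following
how each method defines "expected due to chance". Extra counts are
floored at zero for the peak as a whole; per-bin flooring would bias
every index upward. When flooring engages ($T \le E[C]$), $k'$ is
reported as 1 so that $k' - (k'-1) = 1$ always holds; an empty zscore
peak returns all six indices as 0. SI's denominator uses the counts
inside the ±100 ms analysis window — the indices are defined on the
correlogram actually analyzed. The trial duration defaults to the
concurrent-activity span (later first discharge to earlier last
discharge), the natural normalizer for CIS; pass `trial_duration =` to
use the nominal task length instead.

## The simulator

`simulate_pair()` generates the ground-truth scenario the indices are
meant to estimate. Each baseline train is a renewal process with
Gaussian ISIs truncated at a 10 ms floor — voluntary motor unit firing is
strongly regular, so the CV (default 0.15) is the regularity knob, not a
Poisson assumption. Common input is injected as a Poisson stream of
synchronous events (default 2/s); at each event the nearest upcoming
discharge of each train is *displaced* to the event time plus independent
Gaussian jitter (default SD 1 ms). Displacement, rather than insertion,
models shared input without inflating firing rates, so realized mean ISIs
stay near nominal (defaults 70 and 100 ms over 60 s). Every draw flows
through one user-supplied seed.

What the simulator does *not* emulate: rate modulation (ramps, fatigue),
ISI heavy tails and pauses from real decompositions, doublets, and
decomposition errors. This matters for interpreting tests, as the next
section explains.

## Operating characteristics and a known limitation

The classical premise behind all three detectors is that independent
trains yield a *flat* correlogram across the ±100 ms window, so the
±(60–100) ms bins estimate chance. That premise holds only when the event
train's ISIs are long and/or variable enough for first-order intervals to
populate the whole window. For highly regular trains with mean ISIs of
70–100 ms — exactly the simulator's defaults — first-order intervals are
bounded by the event train's ISI gaps: the correlogram is a plateau with
cliffs near ±70 ms and near-empty bins beyond ±85 ms. Then:

* the baseline region underestimates the central chance level and has a
  large SD (it straddles the cliff);
* the cumsum 10–90% boundaries capture the whole plateau rather than the
  central deflection, inflating peak width (the field's own caveat about
  baseline variability producing "unreasonably large" peaks) and hence
  CIS severalfold;
* the cumsum significance test fires on most *independent* pairs, far
  above its nominal 5%;
* a few central bins exceed the shuffled-null threshold by chance, so
  the zscore method's median CIS on independent pairs is slightly
  positive (~0.1 impulses/s) rather than 0.

The package's validation suite asserts the idealized operating
characteristics at these standard conditions and we report the outcomes
as measured: the zscore method's *detection* behaviour is accurate
(injected 2/s synchrony is detected in essentially every run, with the
peak centered within ±3 ms and CIS ≈ 1.5–2), while the cumsum method's
recovery and type-I behaviour fail in exactly the way the analysis above
predicts. Real recordings, whose ISI distributions have heavier tails,
flatten the correlogram and are much kinder to the cumsum method — which
is why published analyses of real pairs report sensible 10 ms peaks.
Practical advice: check `plot_cumsum()` and the correlogram before
trusting any automated boundary, and prefer the zscore method when
firing is very regular.

```{r correlogram, fig.alt = "Correlogram with zscore peak highlighted"}
autoplot(fit, method = "zscore")
```

```{r cusum, fig.alt = "Normalized cumulative sum"}
plot_cumsum(fit$correlogram)
```

## Numerical choices

* Bin index: `floor(round(x / binwidth, 9))`. The rounding guard only
  snaps values within ~1e-9 bin widths of an edge, protecting
  millisecond-grid timestamps whose double representation falls an ulp
  below the edge; continuous-valued intervals are unaffected.
* Population SD (divide by *n*) everywhere a significance threshold is
  formed — baseline SD and the shuffled-null threshold — matching the
  defining formulas.
* Time comparisons (role ties, zero-lag coincidences) use exact parsed
  values; no epsilon snapping of timestamps.
* Duplicate timestamps within one unit are an error, never silently
  deduplicated: a unit cannot fire twice at one instant, so duplicates
  signal an upstream decomposition fault.
* Degenerate inputs: a zero baseline mean stops the cumulative sum with
  advice (record longer or widen bins); a zero-range cumulative sum and
  a crossed 10/90% ordering fall back to ±5 ms; an empty zscore peak
  propagates zero indices rather than an error.

## Problem sizes used in the validation suite

Deterministic checks run on the published six-point worked example and
constructed 201-bin fixtures. Property checks use 200 random pairs of up
to 50 discharges against a brute-force oracle. Simulation checks use
60 s pairs (roughly 600 and 850 discharges): 25 seeds for rate recovery,
100 seeds for the type-I rate, 20 seeds for detection — sizes at which
the Monte-Carlo error is well below the tolerances asserted.
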