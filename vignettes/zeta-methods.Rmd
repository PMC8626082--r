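---
title: "Methods: the ZETA-test, the binless instantaneous firing rate, and the simulation benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ZETA-test and its benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zetatest)
```

## The problem

A basic screening question in systems neuroscience is whether a neuron
*responds* to a series of events — stimulus onsets, optogenetic pulses,
behavioural triggers. The classical answers either compare mean rates
between a stimulus and a baseline epoch (a paired t-test across trials) or
bin the event-aligned spikes into a peri-stimulus time histogram (PSTH) and
run an ANOVA across bins. Both require choices (epochs, bin widths) that
change the answer, and both miss neurons whose mean rate is unchanged but
whose spike *timing* is reliably event-locked (onset/offset transients,
balanced on/off responses, phase resets).

`zetatest` implements a parameter-free alternative: the ZETA-test
(Zenith of Event-based Time-locked Anomalies), together with a binless
multi-scale instantaneous firing-rate (IFR) estimator for latency
detection, the baseline tests it is compared against, and point-process
simulators plus ROC machinery that validate the test's power and type-I
calibration without any external data.

## The ZETA statistic

Given spike times $x_i$ and event onsets $w_k$, all spikes are expressed
relative to the most recent onset and pooled over trials, keeping relative
times in $(0, \tau]$ for an analysis window $\tau$ (by default the median
onset-to-onset interval). Two sentinel spikes at $0$ and $\tau$ guarantee
coverage; the pooled, sorted vector $v$ has $n$ entries including
sentinels. The fractional position $g_i = i/n$ is the empirical cumulative
distribution of event-aligned spike times sampled at the spikes; an
unmodulated neuron has the linear baseline $b_i = v_i/\tau$. The deviation

$$\delta_i = g_i - b_i, \qquad d_i = \delta_i - \bar\delta$$

is mean-centered, which makes the statistic invariant to the placement of
the event times relative to the response (a circular shift of all onsets
only reorders the set $\{d_i\}$ — the test suite checks this exactly on
ring-wrapped data). The raw statistic is $\zeta_r = \max_i |d_i|$; ties in
the argmax are resolved to the earliest spike time, so the reported
deviation time is deterministic.

## The null distribution and significance

The distribution of $\zeta_r$ under "no event-locking" is unknown, so it
is resampled: each of $P$ iterations (default 100) displaces every event
onset independently by a uniform offset on $[-\tau, +\tau]$, recomputes the
pooled cumulative fraction, linearly interpolates it back onto the original
spike times (clamping outside the resample's support), subtracts the same
baseline $b$, re-centers, and records $\zeta'_{(j)} = \max|d'_{(j)}|$.
Interpolating onto the *original* sample times is what makes the null
curves comparable to the observed one even though the jittered window
captures a different number of spikes.

An alternative null shuffles the inter-spike intervals of the whole train
and rebuilds it from the original first spike, leaving the events
untouched. For a renewal-process neuron the two nulls agree (the suite
checks their $\zeta'$ distributions are indistinguishable for a Poisson
train); for bursting neurons they differ, because ISI shuffling destroys
burst structure while onset jittering preserves it — this is exactly what
the bursting benchmark quantifies.

Since $\zeta_r$ is a sample maximum, its null is approximated by a Gumbel
distribution fit by moment matching: $\beta = \sqrt{6\,\mathrm{Var}
(\zeta')}/\pi$, $m = \overline{\zeta'} - \beta\gamma$ with $\gamma \approx
0.5772$ the Euler–Mascheroni constant, and
$p = 1 - \exp(-\exp(-(\zeta_r - m)/\beta))$. The corrected statistic
$\zeta = \Phi^{-1}(1 - p/2)$ reads as a z-score. The Gumbel shortcut is
validated against the brute-force empirical percentile of $\zeta_r$ among
the null samples (Spearman rank agreement > 0.95 in the acceptance suite).
Two conventions matter in edge cases: a resample that captures fewer than
two spikes contributes $\zeta' = 0$ and is flagged; $p$ is never reported
as exactly zero but clamped to the smallest positive double with a
`saturated` flag.

## Instantaneous firing rate and latencies

The time of the maximum deviation is where the *cumulative* anomaly peaks,
not where the firing rate does. The rate estimate therefore differentiates
$d$: for each spike and each timescale $t_k$ on a base-1.5 logarithmic grid
spanning (1 ms, $\tau$/10), the local slope of $d$ is taken between the
nearest spikes strictly outside $v_i \pm t_k/2$ (window edges snap to the
first/last sample; coincident spikes widen to the nearest distinct
neighbours, and a scale with no usable span contributes zero). Averaging
over scales gives $m_i$; long timescales contribute slopes near zero while
the shortest scales average out noise, so $m$ follows the shortest
timescale at which real structure emerges. The rate is the rescaling

$$r_i = \frac{n}{\tau q}\cdot\frac{m_i + 1/\tau}{\bar m + 1/\tau},$$

where $\bar m$ is the trapezoid time-average of $m$ over the inter-spike
intervals. This guarantees $r \ge 0$ (the slope of $d$ is bounded below by
$-1/\tau$) and conserves the mean rate exactly: the ISI-weighted time
average of $r$ equals $n/(\tau q)$ as an algebraic identity, which the
suite verifies to $10^{-9}$ relative error. One sign convention is worth
noting: the time-average of $m$ is computed with the positive interval
lengths $v_i - v_{i-1}$; a time-weighted mean requires positive weights.

Latencies derive from $r$ sampled at the spike times: peak = global
maximum (earliest on ties), trough = global minimum, onset = the last
crossing of half-maximum before the peak, linearly interpolated between
samples. Half-maximum is referenced to $r_{\min} + (r_{\max} -
r_{\min})/2$ rather than to zero, so a nonzero baseline rate does not bias
the onset; if the rate never dips below half-max before the peak the onset
is clipped to the window start and flagged. The onset search runs backward
from the peak, which pins "first crossing" to the rising flank of the
*dominant* peak rather than to an earlier, smaller fluctuation.

## Baseline tests

* **Paired mean-rate t-test** between per-trial rates in a stimulus epoch
  and a baseline epoch (defaults 0–1 s and 1–1.5 s after onset). Zero
  variance of the paired differences returns p = 1 with a flag — screening
  pipelines need a defined value, and "no difference anywhere" is the null.
* **Optimal-bin PSTH ANOVA**: bin width minimizing the
  Shimazaki–Shinomoto cost $C(\Delta) = (2\bar k - v)/(n_{\text{trials}}
  \Delta)^2$ over trial-pooled per-bin counts ($\bar k$, $v$: mean and
  biased variance across bins). Candidate widths are those that tile the
  window exactly ($\Delta = \tau/n_b$), which removes partial-coverage
  artifacts at the window end, and the cost is evaluated exhaustively over
  all of them rather than by coarse-to-fine refinement: for sharply peaked
  neurons the cost landscape has isolated deep minima (bin/response phase
  alignment) that defeat any multiresolution search, while the admissible
  set on $[1\,\text{ms}, \tau/2]$ is small enough that a full scan costs
  well under a second. The suite confirms exact agreement with an
  independent brute-force evaluation. The ANOVA treats bins as groups and
  per-trial counts as replicates — the only reading that yields
  replicates.
* **Multi-timescale ANOVA**: 19 bin widths on a base-2 grid around one
  movie-frame duration (1/60 s), Bonferroni-corrected minimum p over the
  widths that fit the window.
* **Renewal-process surrogate tests** on 1-ms-binned trial-averaged
  counts: a one-sample KS test against the analytic homogeneous-Poisson
  trial average (a two-sample Monte Carlo variant is available behind a
  flag, since the printed description does not fix the flavour); a
  two-sample KS against ISI-shuffled surrogates; and Gumbel tests of the
  maximum absolute PSTH deviation and of the maximum absolute
  mean-centered cumulative deviation (both centerings applied, so the
  zero-variance fixed points at the ends are removed). The KS variants on
  heavily tied discrete counts have approximate p-values; they are
  benchmarked by rank (ROC), where only the ordering matters.

## Simulators: what they emulate and what they do not

All generators are reproducible from (parameters, seed) and record ground
truth; they emulate event-locked rate modulation, orientation tuning and
burst firing, but not refractory periods, adaptation, drift, or correlated
noise across neurons — so passing benchmarks demonstrates statistical
behaviour under the stated point-process models, not under every
biological spike train.

* **Tuned Poisson neurons**: preferred orientation uniform on $(0, \pi)$,
  baseline rate $\mu_{base} \sim$ Exp(mean 5 Hz), preferred rate
  $\mu_{stim} \sim$ Exp(mean $\mu_{base}$ + 20 Hz), a two-lobe von Mises
  tuning curve (concentration 5 + U(0,5)) rescaled between trough
  $\mu_{base}$ and peak $\mu_{stim}$, 20 repetitions of 8 directions, 1 s
  stimulus + 1 s inter-trial interval, Poisson spiking per epoch. Across
  neurons the mean baseline is 5 Hz and the mean preferred rate 25 Hz.
* **Rate/duration grid**: stimulus-second rate $(1 + dHz)/T_r$ on
  $[0, T_r]$ and zero afterwards, 1 Hz background — total stimulus spike
  count $1 + dHz$ is conserved for every response duration, isolating
  temporal structure from count differences.
* **Bursting neurons**: a ~1 Hz single-spike Poisson process superposed
  with a burst process. Burst intensity during the 1 s stimulus is
  $|R_b| + |R_t|\cdot f_{vM}(\theta;\theta_p,\kappa)$ with $R_b \sim
  |N|/20 + 1/80$ and $R_t \sim |N| + 1/4$ (baseline inter-burst intervals
  of tens of seconds, under a second at the preferred direction), and
  $|R_b|$ during the 0.5 s inter-trial interval; 20 repetitions of 24
  directions. Bursts expand into spikes with gamma-distributed durations
  (shape $2k$, scale 0.5 ms, $k \sim 90 + 10N$ per burst) and intra-burst
  ISIs (same form, $k \sim 0.5 +$ Exp(mean 2.4) per burst). Unresponsive
  neurons burst at a constant per-neuron intensity equal to the time
  average of their own tuned intensity, which matches the two populations'
  firing-rate distributions by construction — the discriminative signal is
  temporal, not rate-based.
* **Peak-latency neurons**: Poisson background (0.5–32 Hz) plus one extra
  spike in half of the trials at $N(\text{center}, \sigma^2)$, center
  uniform in 90–110 ms, $\sigma$ 1–10 ms; ground-truth peak time recorded.
* **Null twins** destroy event-locking for calibration/ROC negatives by
  independent onset jitter (default ± one median onset-to-onset interval)
  or per-train ISI shuffling.

### Design choices in the bursting generator

Three points of the bursting parameterization were genuinely open and were
fixed as follows, once, on internal-consistency grounds:

1. *Exponential parameter convention.* The burst tables state inter-burst
   intervals as Exp$(1/|R|)$; only the mean convention (an exponential with
   mean $1/|R|$, i.e. intensity $|R|$) produces the stated tens-of-seconds
   baseline intervals — the rate convention would give ~50 ms. The same
   convention is therefore applied to every exponential hyper-parameter,
   including the intra-burst ISI scale (mean 2.4 ms). This reading also
   reproduces the spread (quartile ratio ~3) of the published firing-rate
   distribution, which the rate convention does not.
2. *Where tuning acts.* Tuned burst intensity is confined to the stimulus
   epoch. The alternative (tuning the whole trial) removes all within-trial
   temporal structure and makes every test perform at chance, which cannot
   be the benchmark's intent.
3. *Per-burst parameter draws.* Burst duration and intra-burst ISI scales
   are redrawn for every burst from their stated hyper-distributions; the
   neuron-level identity lives in the intensity parameters
   ($R_b, R_t, \theta_p, \kappa$) and the single-spike rate. Freezing the
   gamma scales per neuron instead produces a markedly lower and more
   dispersed population rate distribution than published.

With these choices the responsive population's 25th rate percentile and
the inter-burst-interval scales match the published values; the 75th
percentile comes out lower (~13 Hz rather than ~19.7 Hz), an acknowledged
residual of the parameter table's ambiguity that is surfaced, not hidden,
by the acceptance checks.

## Benchmarks and problem sizes

The ROC machinery sweeps the significance level over the observed
p-values; the AUC is the trapezoid area, which equals the
Wilcoxon–Mann–Whitney rank statistic exactly (ties credited 1/2; verified
against explicit pairwise counting). Inclusion/false-positive rates carry
exact binomial 95% confidence intervals.

The shipped benchmark sizes are the package's defaults: 250 neurons per
class with 100 resamples for the bursting power benchmark, 1000
event-jittered tuned-Poisson neurons for type-I calibration, 10 peak
widths × 30–50 neurons at a 32 Hz background for the latency benchmark
(PSTH comparison grid 1.00–57.67 ms, base 1.5), 10,000 neurons
(rate parameters only) for the tuned-Poisson generator self-check. These
sizes put the Monte-Carlo error of an AUC near 0.01–0.02 and of a
rejection rate near 0.7 percentage points, adequate for the documented
tolerances; larger runs are a matter of raising the arguments.

## Numerical conventions and degenerate inputs

* Duplicate spike times are kept everywhere; sorting is stable, the
  cumulative-fraction interpolation collapses ties to the upper CDF value,
  and the multi-scale derivative widens coincident windows to distinct
  neighbours.
* A neuron with no spikes in any event window yields p = 1 with a
  `no_spikes` flag rather than an error; a degenerate null (zero variance)
  is an error, since no significance statement is possible.
* Events whose windows extend past the last spike are used as-is; the
  sentinel construction handles coverage, and no edge trimming is applied.
* Every stochastic operation takes an explicit integer seed; population
  runners derive per-neuron seeds deterministically from it.
* The jitter magnitude is $\pm\tau$ with $\tau$ the analysis window, whose
  default is the median onset-to-onset interval — unifying the two ways
  the jitter width is commonly stated. Whether events are jittered
  independently (implemented) or by a shared per-resample offset is a
  sensitivity worth knowing about; independent jitter is the literal
  reading of "move each event time".

## Known limitations

* The Gumbel fit is a two-moment approximation; at P = 100 resamples its
  tail p-values below ~$10^{-3}$ are extrapolations. Rank-based summaries
  (ROC/AUC) are insensitive to this; absolute tiny p-values should be
  read as "very significant", not as literal probabilities.
* The ISI-shuffle null assumes exchangeable inter-spike intervals and is
  anticonservative for strongly bursting neurons — demonstrated, not
  hidden, by the bursting benchmark (it is the point of that comparison).
* The KS-based surrogate tests inherit the discreteness issues of
  KS-on-counts; they are included as comparison baselines, not as
  recommended tests.
* The simulators sample independent neurons; population-level correlation
  structure is out of scope.
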