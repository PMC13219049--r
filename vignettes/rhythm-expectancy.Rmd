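---
title: "Rhythmic expectancy with recurrent timing nets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rhythmic expectancy with recurrent timing nets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timingnets)
```

## The model

A recurrent timing net (RTN) is an array of delay loops attached to
coincidence elements. The input is a binary pulse train $X(t) \in \{0,1\}$
on a fixed timestep grid (default $\Delta t = 50$ ms). Each loop $i$ has a
recurrence time $\tau_i$ (in timesteps) and carries a circulating copy of
the recent input, so the signal arriving back at its coincidence element at
time $t$ is

$$Y_i(t) = X(t - \tau_i),$$

which is loop $i$'s prediction of $X(t)$: the loop bets that the input
repeats with period $\tau_i$. The loop's current credibility is the Pearson
correlation between the input's last two lag-$\tau_i$ windows,

$$r_i(t) = \mathrm{corr}\big(X[t-\tau_i \,..\, t-1],\; X[t-2\tau_i \,..\, t-\tau_i-1]\big),$$

its running evidence that the input actually is $\tau_i$-periodic. Negative
correlations are clipped to zero by default (an anti-correlated loop
abstains rather than casting an inverted vote), giving an effective
correlation $c_i(t) \in [0,1]$. Each loop then votes its prediction with
weight proportional to its correlation and its duration,

$$w_i(t) = c_i(t)\, \tau_i,$$

and the network compares the summed weights of loops predicting a pulse
($S_1$) against those predicting silence ($S_0$), winner-take-all:
$\hat{y}(t) = 1$ iff $S_1 > S_0$, with ties resolved toward silence. After
$X(t)$ is observed, the prediction error is the vote margin on a wrong
call,

$$E(t) = |S_1(t) - S_0(t)| \cdot \mathbb{1}[\hat{y}(t) \neq X(t)],$$

reported both raw and normalized by its per-trace maximum. Timesteps with
$E(t) > 0$ are *expectancy violations*, classified as an unexpected event
($\hat y = 0$, $x = 1$) or a missing event ($\hat y = 1$, $x = 0$) — the
model's analogue of a deviance (oddball) response.

Loops whose delay matches an event periodicity — the repetition period or
any multiple of it — saturate at $c_i = 1$ and dominate the vote, which is
how repeating patterns "build up" in matching delay paths: over the delay
axis, `loop_spectrum()` is effectively a running autocorrelogram of the
input.

## Conventions and why

Several details are underdetermined by the verbal description above; the
package fixes them as follows.

**Window convention.** The two correlation windows are half-open and end at
$t - 1$: the prediction at $t$ never uses $X(t)$. Predictions must precede
observations.

**Unpopulated loops.** A loop needs $t \ge \tau$ before its circulating
value exists and $t \ge 2\tau$ before it has two full windows to correlate.
Until then it contributes nothing ([`lagged_value()`] and
[`two_period_correlation()`] signal distinct conditions; `network_step()`
simply skips such loops). A step at which *no* loop is populated therefore
has $S_0 = S_1 = 0$ and predicts silence; note that a mismatch at such a
step carries zero error magnitude, since the error is defined as the vote
margin. Everywhere that at least one loop is active, $E(t) > 0$ exactly
when $\hat y(t) \ne X(t)$ up to exact vote ties.

**Zero-variance windows.** Pearson correlation is undefined for constant
windows, which are ubiquitous with sparse binary input (any all-silent
window is constant). The default rule, `zero_variance_rule = "match"`,
scores 1 when the two windows are identical and 0 otherwise. This makes
sustained silence itself an expected pattern: an all-zero history predicts
continuing silence, so a stimulus onset after silence produces a genuine
violation with positive magnitude, and the offset of an established rhythm
produces missing-event violations against the still-circulating pattern.
The alternative `"zero"` (constant windows carry no evidence) is provided
for sensitivity analysis; under it the network still predicts silence on
silent input (via the tie-break) but silence onsets carry no error
magnitude.

**Duration weighting.** "Weight by loop duration" could in principle run
either way; the package reads it as $w \propto \tau$ — a long pair of
agreeing windows is more evidence of periodicity than a short one, exactly
as longer-lag autocorrelations are computed over more structure. `"uniform"`
weighting is available for comparison.

**Tie-break.** $S_1 = S_0$ predicts 0, consistent with silence as the
default expectation.

**Circulation as lagged reads.** Loops are realized as lagged reads of a
single input-history buffer. This is observationally identical to per-loop
circulating ring buffers ($Y_i(t) = X(t - \tau_i)$ either way) and is the
contract the tests pin down; the mechanism is not normative.

**Delay set.** Default: all integers $1..\tau_{max}$ with $\tau_{max}$
twice the longest repetition period under study, so the period and its
first subharmonic both have loops (`default_config_for()`).

**Error normalization.** Per-trace maximum maps to 1; all-zero error traces
are left at zero rather than dividing 0/0.

## Stimuli and the latency code

`make_isochronous()` and `make_repeating_pattern()` construct the basic
paradigms on the integer grid. Event *attributes* (loudness, pitch, timbre
categories) are encoded by `encode_events()` as pulse latencies relative to
an onset-locked burst: with a slot at base latency $b$ holding $n$ values,
value $v$ becomes a pulse at $\mathrm{onset} + b + v$. The layout choices —
a single-pulse burst at offset 0, slots packed contiguously after the
burst, one timestep per value step — are engineering defaults, configurable
through `multiplex_codec()`. Encoding refuses collisions (two pulses on one
timestep) and footprints that do not fit the inter-onset interval, rather
than silently merging, so `decode_events()` recovers every valid pattern
exactly.

`inject_deviant()` perturbs an established stimulus the way oddball
paradigms do — omission, timing shift, attribute change, tempo change,
pattern change — and records the altered timesteps, so analyses can ask
whether violations line up with the injected deviance.

## What the generator emulates — and what it does not

`random_primitive_cycle()` draws dense binary grid rhythms: each grid point
carries a pulse with probability 0.5, rejecting cycles whose minimal period
is shorter than requested. Dense grid patterns of this kind are the
standard random-rhythm material in perception experiments, and at the
default 50 ms timestep the sweep periods (3–16 steps, 0.15–0.8 s) span
musical repetition rates. The generator does *not* emulate: graded event
intensities (input is strictly binary), timing jitter (events sit exactly
on the grid), or the co-occurrence statistics of real music (pulses are
independent across grid points). Passing tests therefore show that the
network tracks and predicts exactly repeating binary patterns and flags
their violations — not that it is robust to noisy, expressive performance
timing.

## Behavior, measured

The analysis layer defines the observables the demonstrations use:

* `detect_violations()` — the positive-error timesteps, classified.
* `adaptation_time()` — repetitions of a pattern until the trace is
  violation-free: $t_{stable}$ is the first timestep from which no
  violations occur up to the horizon, and repetitions
  $= \lceil (t_{stable} - \mathrm{start}) / P \rceil$. "Adapted" means
  *strictly zero* violations to the horizon — with binary signals and
  deterministic updates, graded criteria add nothing, and the error traces
  of adapted runs are exactly zero. If violations persist through the
  horizon the result is `Inf`.
* `fill_in_check()` — whether $\hat y = 1$ at an omitted beat: the
  network's expectancy fills in the missing event.

The bundled scenarios (problem sizes chosen to keep every run in the
seconds range): isochronous onset/offset (period 4, 8 events, lead silence
8, tail 12, loops 1..16); omission of beat 6 of 8 (tail 0, so the analysis
window ends with the pattern — the offset response is its own scenario);
tempo change 4 → 6 at event 6 of 14; pattern change between two period-6
cycles at cycle 5 of 9; attribute change (latency-coded value 1 → 3 from
event 6 of 9, period 10, loops 1..20). The adaptation sweep uses 20 random
primitive cycles, periods 3–16, six cycles each, loops 1..32.

In these scenarios the network shows the expected qualitative repertoire:
violations at stimulus onset until the loops populate; silent tracking of
the established rhythm; missing-event fill-in at an omitted beat (with
exactly one missing-event violation at the omitted slot); pop-out at tempo,
pattern and attribute deviants followed by re-adaptation within at most two
repetitions of the new pattern; and renewed missing-event violations when
the stimulus ends and the circulating pattern outlives it.

## Known limitations

* **Sub-periodic coalitions can stall cold-start adaptation.** For cycles
  that contain strong internal periodicity (e.g. a period-8 cycle ending in
  a period-2 alternation, `00010101`), the loops at the sub-period and its
  multiples ($\tau = 2, 4, 6, 10, \dots$) hold high partial correlations
  wherever the sub-pattern holds, and their summed, duration-weighted votes
  can permanently outvote the exactly-correlated loops at multiples of the
  true period at the cycle positions where the sub-pattern breaks. Such
  patterns never become violation-free from a cold start under the default
  sum-of-weighted-votes rule — the violation recurs once per cycle
  indefinitely — and in random-cycle sweeps a substantial fraction of
  patterns (at any pulse density) adapt in more than two repetitions for
  this reason. *Re*-adaptation after a change to an established rhythm, by
  contrast, is reliably within two repetitions in the bundled scenarios.
  The summed vote treats partially correlated loops as independent
  evidence, which they are not; down-weighting redundant sub-period loops
  is the obvious refinement, but it is not part of the model as defined.
* The model is deterministic and noise-free; it makes no quantitative
  claims about neurophysiological deviance responses (amplitudes,
  latencies), only the qualitative error-trace analogy.
* Correlations within a loop are unweighted over their window; recency
  weighting and loop–loop interactions (cross-correlation of loop outputs,
  feedback of loop outputs into the input) are out of scope.
* Continuous-amplitude (e.g. half-wave-rectified waveform) inputs are not
  supported: pulses are strictly binary.

## A worked run

```{r demo, eval = FALSE}
train <- scenario_stimulus("omission")        # beat 6 of 8 deleted, period 4
trace <- rtn_run(train, default_config_for(train))
detect_violations(trace)
#>    t             kind  magnitude
#> 1  8 unexpected_event 0.90909091
#> 2 12 unexpected_event 0.09090909
#> 3 28    missing_event 1.00000000
#> 4 32 unexpected_event 0.06934278
#> 5 36 unexpected_event 0.56702085
fill_in_check(trace, train$meta$omitted_t)
#> [1] TRUE
render_raster(train, trace, "omission.png")
```

The onset violations at $t = 8, 12$ are the build-up; the lone
missing-event violation at $t = 28$ is the omitted beat, filled in by the
network ($\hat y = 1$) with the largest error magnitude in the trace; the
violations at the two following beats ($t = 32, 36$) are the after-effect
of the gap passing through the loop windows, suppressing the pulse
expectancy there.
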