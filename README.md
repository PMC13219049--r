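# timingnets

Recurrent neural timing nets (RTNs) for rhythmic expectancy and deviance
detection.

## What this is

How does a listener come to *expect* the next beat — and notice, within a
beat or two, when a rhythm skips, shifts, or changes character? This
package implements a correlation-based adaptive predictive model of that
process for researchers in auditory perception and computational
neuroscience: an array of delay loops and coincidence detectors operating
on temporally coded input, i.e. binary pulse trains X(t) ∈ {0,1} on a
fixed timestep grid (default Δt = 50 ms).

Each loop *i* with recurrence time τᵢ carries a circulating copy of the
recent input, so its prediction of the current timestep is

    Yᵢ(t) = X(t − τᵢ)

— the loop bets the input repeats with period τᵢ. Its credibility is the
Pearson correlation rᵢ(t) between the input's last two lag-τᵢ windows,
rectified to cᵢ(t) ∈ [0, 1] and weighted by loop duration, wᵢ = cᵢ·τᵢ.
The network compares the summed weights of loops voting "pulse" (S₁)
against "silence" (S₀), winner-take-all:

    ŷ(t) = 1  iff  S₁ > S₀        (ties → silence)
    E(t) = |S₁ − S₀|  when ŷ(t) ≠ X(t), else 0

Timesteps with E(t) > 0 are expectancy violations — missing events
(predicted pulse, silence arrived) or unexpected events (pulse arrived
unpredicted) — the model's analogue of an oddball deviance response.
Repeating patterns build up in loops whose delay matches the repetition
period or its multiples; over the delay axis the loop array behaves as a
running autocorrelogram (`loop_spectrum()`).

Around the core the package provides stimulus generators for the standard
paradigms (isochronous sequences, repeating cycles, latency-multiplexed
event attributes, oddball deviants: omission, timing shift, tempo change,
pattern change, attribute change), analysis of violations, adaptation time
and missing-beat fill-in, plain-text formats for onset lists, pulse grids
and traces, raster figures, and a small CLI.

## Worked example: the missing beat

```r
library(timingnets)

train <- scenario_stimulus("omission")   # period 4, 8 events, beat 6 deleted
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
```

Reading the output: the rhythm starts at t = 8 after lead silence, and the
first two beats (t = 8, 12) violate the silence expectancy while the loops
populate — the build-up. From the third beat the network tracks the rhythm
silently. At the omitted beat (t = 28) the network still predicts a pulse
(`fill_in_check` is `TRUE`): the expectancy fills in the missing event,
and the mismatch with the incoming silence is the largest error in the
trace (magnitude 1.00). The two beats after the gap show the omission's
after-effect passing through the loop windows.

`render_raster(train, trace, "omission.png")` draws the standard figure:
stimulus bars on top, predicted pulses below in red, open bars for error
magnitude, dashed lines at violations, dotted lines at injected deviants.

From a shell, the same experiment end to end:

```sh
Rscript inst/cli/rtn.R demo --scenario omission --out demo-out --seed 1
```

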