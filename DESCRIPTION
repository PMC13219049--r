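Package: timingnets
Title: Recurrent Neural Timing Nets for Rhythmic Expectancy and Deviance
    Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates recurrent neural timing nets (RTNs): arrays of delay
    loops and coincidence detectors that track repeating temporal patterns
    in binary pulse trains. Each loop with delay tau predicts that the
    input repeats with period tau; loops are weighted by the Pearson
    correlation of the last two lag-tau windows of input and by loop
    duration, and a winner-take-all vote over the weighted loops yields
    the network's per-timestep expectancy and prediction-error trace.
    Includes stimulus generators for rhythmic paradigms (isochronous
    sequences, repeating patterns, latency-multiplexed event attributes,
    oddball deviants such as omissions, timing shifts, tempo and pattern
    changes), analysis of expectancy violations, adaptation time and
    missing-beat fill-in, plain-text file formats for onset lists, pulse
    grids and prediction traces, and raster plots of stimulus, expectancy
    and error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
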