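test_that("make_isochronous places pulses at lead + k * period", {
  tr <- make_isochronous(period = 4, n_events = 3, lead_silence = 2, tail_silence = 2)
  expect_equal(tr$x, c(0L, 0L, 1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 1L, 0L, 0L))
  expect_equal(tr$onsets, c(2L, 6L, 10L))
  expect_equal(tr$period, 4L)

  # degenerate period 1: back-to-back pulses
  expect_equal(make_isochronous(1, 5)$x, rep(1L, 5))

  # length formula
  tr2 <- make_isochronous(6, 4)
  expect_length(tr2$x, 19L)
  expect_equal(sum(tr2$x), 4L)

  expect_error(make_isochronous(0, 3), class = "timingnets_invalid_argument")
  expect_error(make_isochronous(4, 0), class = "timingnets_invalid_argument")
})

test_that("make_repeating_pattern concatenates cycles and records the period", {
  tr <- make_repeating_pattern(c(1, 0, 1, 0, 0), n_cycles = 2)
  expect_equal(tr$x, c(1L, 0L, 1L, 0L, 0L, 1L, 0L, 1L, 0L, 0L))
  expect_equal(tr$period, 5L)

  # base of one pulse reduces to the isochronous special case
  expect_equal(make_repeating_pattern(1, 4)$x, make_isochronous(1, 4)$x)

  expect_error(make_repeating_pattern(integer(0), 2),
               class = "timingnets_invalid_argument")
})

test_that("every cycle of a repeated pattern equals the base", {
  set.seed(11)
  for (rep_i in 1:10) {
    p <- sample(3:9, 1)
    base <- random_primitive_cycle(p)
    n_cycles <- sample(2:5, 1)
    lead <- sample(0:6, 1)
    tr <- make_repeating_pattern(base, n_cycles, lead_silence = lead)
    expect_equal(sum(tr$x), n_cycles * sum(base))
    for (k in seq_len(n_cycles)) {
      cyc <- tr$x[lead + (k - 1L) * p + seq_len(p)]
      expect_identical(cyc, base)
    }
  }
})

test_that("random_primitive_cycle draws cycles with the exact minimal period", {
  set.seed(3)
  for (p in c(2, 4, 6, 8, 9, 12, 16)) {
    base <- random_primitive_cycle(p)
    expect_length(base, p)
    expect_gt(length(unique(base)), 1L)
    # no proper divisor d of p reproduces the cycle
    for (d in seq_len(p - 1)[p %% seq_len(p - 1) == 0]) {
      expect_false(all(base == rep_len(base[seq_len(d)], p)))
    }
  }
})

test_that("encode_events places burst and latency-coded attribute pulses", {
  codec <- multiplex_codec(dt = 0.05, onset_burst = 0L, slots = list(attr = c(2L, 4L)))
  # one event at t = 10, value 3 -> pulses at 10 and 10 + 2 + 3 = 15
  pat <- event_pattern(10 * 0.05, attributes = data.frame(attr = 3L),
                       duration = 20 * 0.05)
  tr <- encode_events(pat, codec)
  expect_equal(which(tr$x == 1L) - 1L, c(10L, 15L))
  expect_equal(tr$onsets, 10L)

  # no attributes: onset pulse only
  pat0 <- event_pattern(10 * 0.05, duration = 20 * 0.05)
  tr0 <- encode_events(pat0, multiplex_codec(dt = 0.05))
  expect_equal(which(tr0$x == 1L) - 1L, 10L)

  # two events, period 20, values 1 then 2
  pat2 <- event_pattern(c(10, 30) * 0.05, attributes = data.frame(attr = c(1L, 2L)),
                        duration = 40 * 0.05)
  tr2 <- encode_events(pat2, codec)
  expect_equal(which(tr2$x == 1L) - 1L, c(10L, 13L, 30L, 34L))
})

test_that("encode_events refuses off-grid onsets, range and footprint breaches", {
  codec <- multiplex_codec(dt = 0.05, slots = list(attr = c(1L, 8L)))
  expect_error(
    encode_events(event_pattern(0.512, duration = 2), codec),
    class = "timingnets_encoding_error")
  expect_error(  # value outside the slot range
    encode_events(event_pattern(0.5, attributes = data.frame(attr = 9L),
                                duration = 2), codec),
    class = "timingnets_encoding_error")
  expect_error(  # events closer than the codec footprint
    encode_events(event_pattern(c(0.5, 0.7), attributes = data.frame(attr = c(0L, 0L)),
                                duration = 2), codec),
    class = "timingnets_encoding_error")
  expect_error(  # attribute the codec has no slot for
    encode_events(event_pattern(0.5, attributes = data.frame(other = 1L),
                                duration = 2), codec),
    class = "timingnets_encoding_error")
})

test_that("codec slot windows must be disjoint from each other and the burst", {
  expect_error(multiplex_codec(onset_burst = 0L, slots = list(a = c(0L, 4L))),
               class = "timingnets_invalid_argument")
  expect_error(multiplex_codec(slots = list(a = c(1L, 4L), b = c(3L, 2L))),
               class = "timingnets_invalid_argument")
  # contiguous auto-packing puts slots just after the burst
  codec <- multiplex_codec(onset_burst = c(0L, 1L), slots = c(a = 3L, b = 2L))
  expect_equal(codec$slots$base, c(2L, 5L))
  expect_equal(codec$footprint, 7L)
})

test_that("encode then decode round-trips random latency-coded patterns", {
  set.seed(19)
  codec <- multiplex_codec(dt = 0.05, onset_burst = 0L,
                           slots = c(loudness = 4L, pitch = 6L))
  for (rep_i in 1:20) {
    pat <- random_coded_pattern(sample(2:8, 1), codec)
    dec <- decode_events(encode_events(pat, codec), codec)
    expect_equal(dec$times, pat$times)
    expect_identical(dec$attributes, pat$attributes)
    expect_equal(dec$duration, pat$duration)
  }
})

test_that("omission clears exactly the advertised pulse", {
  tr <- make_isochronous(4, 6, lead_silence = 2)
  dev <- inject_deviant(tr, "omission", event = 3)
  target <- tr$onsets[3]
  expect_equal(dev$deviants, target)
  expect_equal(dev$meta$omitted_t, target)
  expect_equal(dev$x[target + 1L], 0L)
  expect_equal(which(dev$x != tr$x) - 1L, target)   # single-bit edit
  expect_error(inject_deviant(tr, "omission", event = 7),
               class = "timingnets_invalid_argument")
})

test_that("timing_shift moves one onset pulse by the given offset", {
  tr <- make_isochronous(5, 5)
  dev <- inject_deviant(tr, "timing_shift", event = 4, shift = 1)
  o <- tr$onsets[4]
  expect_equal(sort(dev$deviants), sort(c(o, o + 1L)))
  expect_equal(which(dev$x != tr$x) - 1L, sort(c(o, o + 1L)))
  expect_equal(dev$onsets[4], o + 1L)
  # shifting onto an existing pulse or out of range is refused
  expect_error(inject_deviant(tr, "timing_shift", event = 4, shift = 5),
               class = "timingnets_invalid_argument")
  expect_error(inject_deviant(tr, "timing_shift", event = 5, shift = 100),
               class = "timingnets_invalid_argument")
})

test_that("attribute_change relocates the slot pulse by codec arithmetic", {
  codec <- multiplex_codec(dt = 0.05, slots = list(attr = c(2L, 4L)))
  pat <- event_pattern(c(10, 30) * 0.05, attributes = data.frame(attr = c(1L, 1L)),
                       duration = 2)
  tr <- encode_events(pat, codec)
  dev <- inject_deviant(tr, "attribute_change", event = 2, attribute = "attr",
                        new_value = 3)
  # value 1 -> 3 moves the slot pulse 2 timesteps later: 33 -> 35
  expect_equal(sort(dev$deviants), c(33L, 35L))
  expect_equal(which(dev$x != tr$x) - 1L, c(33L, 35L))
  expect_equal(dev$meta$pattern$attributes$attr, c(1L, 3L))
  expect_error(inject_deviant(tr, "attribute_change", event = 2,
                              attribute = "attr", new_value = 4),
               class = "timingnets_invalid_argument")
})

test_that("tempo_change respaces later events and records all changed steps", {
  tr <- make_isochronous(4, 8, lead_silence = 2)
  dev <- inject_deviant(tr, "tempo_change", at_event = 3, new_period = 6)
  anchor <- tr$onsets[3]
  expect_equal(dev$onsets, c(tr$onsets[1:3], anchor + 6L * (1:5)))
  expect_equal(dev$period, 6L)
  # advertised deviants are exactly the aligned bitwise diff
  n <- max(length(tr$x), length(dev$x))
  oldp <- c(tr$x, integer(n - length(tr$x)))
  newp <- c(dev$x, integer(n - length(dev$x)))
  expect_equal(dev$deviants, which(oldp != newp) - 1L)
  expect_equal(dev$meta$change_point, min(dev$deviants))
})

test_that("pattern_change switches the cycle from a cycle boundary onward", {
  base <- c(1L, 0L, 1L, 0L, 0L, 0L)
  new_base <- c(1L, 1L, 0L, 0L, 1L, 0L)
  tr <- make_repeating_pattern(base, n_cycles = 6, lead_silence = 4)
  dev <- inject_deviant(tr, "pattern_change", at_cycle = 4, new_base = new_base)
  # cycles 1..3 untouched, 4..6 are the new cycle
  expect_identical(dev$x[4 + seq_len(18)], rep(base, 3))
  expect_identical(dev$x[4 + 18 + seq_len(18)], rep(new_base, 3))
  expect_gte(min(dev$deviants), 4 + 18)
  expect_equal(dev$meta$change_point, min(dev$deviants))
  expect_equal(dev$period, 6L)
})

test_that("pulse trains validate their values and onset annotations", {
  expect_error(pulse_train(c(0, 2, 1)), class = "timingnets_invalid_argument")
  expect_error(pulse_train(integer(0)), class = "timingnets_invalid_argument")
  expect_error(pulse_train(c(1, 0, 1), onsets = 1L),
               class = "timingnets_invalid_argument")
  expect_error(event_pattern(c(0.2, 0.1), duration = 1),
               class = "timingnets_invalid_argument")
  expect_error(event_pattern(c(0.2, 1.2), duration = 1),
               class = "timingnets_invalid_argument")
})
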