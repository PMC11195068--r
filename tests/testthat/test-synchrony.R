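test_that("observed and chance overlap match direct counting", {
  expect_equal(observed_overlap(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.25)
  p6 <- rep(c(1, 0), c(6, 4))
  expect_equal(observed_overlap(p6, p6), 0.6)           # identical traces
  expect_equal(observed_overlap(c(1, 0), c(0, 1)), 0)   # disjoint
  expect_equal(chance_overlap(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.25)
  expect_equal(chance_overlap(c(0, 0), c(1, 0)), 0)
  expect_equal(chance_overlap(rep(1, 10), rep(c(1, 0), c(3, 7))), 0.3)
  expect_error(observed_overlap(c(1, 0), c(1, 0, 0)), "equal length")
})

test_that("binomial null spread matches its closed form", {
  # p_a = p_b = 0.5 over 480 frames: E = 0.25, sd = sqrt(E(1-E)/480)
  a <- rep(c(1, 0), 240)
  b <- rep(c(1, 1, 0, 0), 120)
  sd0 <- null_overlap_spread(a, b, method = "binomial")
  expect_equal(as.numeric(sd0), sqrt(0.25 * 0.75 / 480), tolerance = 1e-12)
  expect_equal(attr(sd0, "null_mean"), 0.25)
})

test_that("circular-shift null matches exhaustive rotation enumeration", {
  set.seed(42)
  for (n in c(16L, 48L, 64L)) {
    a <- bout_like_trace(n)
    b <- bout_like_trace(n)
    oracle <- rotation_overlaps(a, b)
    got <- null_overlap_spread(a, b, method = "circular_shift",
                               n_surrogates = 1000L)
    expect_equal(attr(got, "null_mean"), mean(oracle), tolerance = 1e-12)
    m <- mean(oracle)
    expect_equal(as.numeric(got), sqrt(mean((oracle - m)^2)), tolerance = 1e-12)
    # surrogate mean overlap approximates the chance overlap; exactly,
    # mean over nonzero rotations = (n E - O) / (n - 1)
    n_len <- length(a)
    expect_equal(attr(got, "null_mean"),
                 (n_len * chance_overlap(a, b) - observed_overlap(a, b)) / (n_len - 1),
                 tolerance = 1e-12)
  }
})

test_that("degenerate traces are flagged instead of scored", {
  expect_warning(out <- null_overlap_spread(rep(1, 200), rep(c(1, 0), 100)),
                 "degenerate")
  expect_true(is.na(out))
  expect_warning(rs <- raw_synchrony(trace_a = rep(c(1, 0), 100),
                                     trace_b = rep(0, 200)), "degenerate")
  expect_true(is.na(rs$raw))
})

test_that("raw synchrony standardizes observed minus chance overlap", {
  # identical traces, p = 0.5, binomial null over 480 frames
  a <- rep(c(1, 0), 240)
  rs <- raw_synchrony(trace_a = a, trace_b = a, method = "binomial")
  expect_equal(rs$raw, (0.5 - 0.25) / sqrt(0.25 * 0.75 / 480), tolerance = 1e-9)
  # O = E gives exactly 0
  ax <- rep(c(1, 0), 8)           # p = 0.5
  bx <- rep(c(1, 0, 0, 1), 4)     # p = 0.5, O = 0.25 = E
  rs0 <- raw_synchrony(trace_a = ax, trace_b = bx, method = "binomial")
  expect_equal(rs0$raw, 0)
  # perfectly anti-aligned traces score negative
  rneg <- raw_synchrony(trace_a = rep(c(1, 0), 240), trace_b = rep(c(0, 1), 240),
                        method = "binomial")
  expect_lt(rneg$raw, 0)
})

test_that("raw synchrony of independent traces is centered near zero", {
  set.seed(7)
  vals <- replicate(400, {
    a <- bout_like_trace(120L)
    b <- bout_like_trace(120L)
    raw_synchrony(trace_a = a, trace_b = b, method = "circular_shift",
                  n_surrogates = 119L)$raw
  })
  # null scores are ~N(0,1): the mean of 400 replicates stays within 0.15
  expect_lt(abs(mean(vals, na.rm = TRUE)), 0.15)
})

test_that("freezing-probability trace is a centered moving average", {
  # flat input stays flat
  flat <- freezing_probability_trace(list(rep(1L, 40), rep(1L, 40)), fps = 4)
  expect_true(all(flat$mean == 1))
  expect_true(all(flat$sd == 0))
  # single ramp trace, 4-frame window: compare to a direct oracle
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)
  got <- freezing_probability_trace(list(x), fps = 4, window_s = 1)
  oracle <- sapply(seq_along(x), function(i) {
    lo <- max(1, i - 1); hi <- min(length(x), i + 2)  # centered 4-frame window
    mean(x[lo:hi])
  })
  expect_equal(got$mean, oracle)
  # SD is zero iff all traces identical
  two <- freezing_probability_trace(list(x, rev(x)), fps = 4)
  expect_true(any(two$sd > 0))
  expect_error(freezing_probability_trace(list()), "non-empty")
})
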