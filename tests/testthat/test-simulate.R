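test_that("simulated ethograms satisfy every annotation invariant", {
  cfgs <- list(
    sim_config(),
    sim_config(gamma_follow = 4),
    sim_config(gamma_retroact_freeze = 4, gamma_retroact_move = 2),
    sim_config(buffering_shift = 1)
  )
  for (cfg in cfgs) {
    for (s in 1:3) {
      d <- simulate_dyad(cfg, seed = s, dyad_id = paste0("v", s))
      for (eth in list(d$ethogram_a, d$ethogram_b)) {
        expect_silent(validate_ethogram(eth))  # min bout, ordering, gaps, bounds
        expect_true(all(eth$bouts$end - eth$bouts$start >= 4L))
      }
    }
  }
})

test_that("a fixed seed reproduces bit-identical bout tables", {
  cfg <- sim_config(gamma_follow = 1)
  d1 <- simulate_dyad(cfg, seed = 7, dyad_id = "dA")
  d2 <- simulate_dyad(cfg, seed = 7, dyad_id = "dA")
  expect_identical(write_bout_table(list(d1$ethogram_a, d1$ethogram_b)),
                   write_bout_table(list(d2$ethogram_a, d2$ethogram_b)))
  d3 <- simulate_dyad(cfg, seed = 8, dyad_id = "dA")
  expect_false(identical(d1$ethogram_a$bouts, d3$ethogram_a$bouts))
})

test_that("cohort simulation derives per-dyad seeds and parameter spreads", {
  co <- simulate_cohort(sim_config(), n_dyads = 23L, seed = 4,
                        sex_composition = "FF",
                        gamma_follow_range = c(0.5, 3))
  expect_length(co$dyads, 23L)
  expect_equal(nrow(co$params), 23L)
  expect_true(all(co$params$gamma_follow >= 0.5 & co$params$gamma_follow <= 3))
  expect_gt(stats::sd(co$params$gamma_follow), 0)
  expect_gt(length(unique(vapply(co$dyads, function(d)
    nrow(d$ethogram_a$bouts), integer(1)))), 1L)
  # order independence: the same dyad id gives the same realization
  flat <- simulate_cohort(sim_config(), n_dyads = 6L, seed = 4)
  lone <- simulate_dyad(sim_config(), seed = 4, dyad_id = flat$params$dyad_id[5])
  expect_identical(lone$ethogram_a$bouts, flat$dyads[[5]]$ethogram_a$bouts)
})

test_that("cohort freezing reproduces the CS-locked rise then decline", {
  co <- simulate_cohort(sim_config(), n_dyads = 30L, seed = 21)
  traces <- do.call(c, lapply(co$dyads, function(d)
    list(bouts_to_trace(d$ethogram_a), bouts_to_trace(d$ethogram_b))))
  fracs <- vapply(traces, mean, numeric(1))
  expect_gt(mean(fracs), 0.30)  # cohort mean CS freezing within 30-70%
  expect_lt(mean(fracs), 0.70)
  fp <- freezing_probability_trace(traces, fps = 4)
  # peak freezing level is reached within 5 s of CS onset (the curve then
  # plateaus, so the literal argmax frame is sampling noise)
  expect_gte(max(fp$mean[fp$time_s <= 5]), 0.95 * max(fp$mean))
  # slow decline: last third clearly below the early peak
  expect_lt(mean(fp$mean[fp$time_s > 80]), max(fp$mean[fp$time_s <= 5]) - 0.2)
  # pre-CS freezing is low by comparison
  pre <- vapply(co$dyads, function(d)
    mean(bouts_to_trace(d$ethogram_a, pre_cs_window(d$ethogram_a$layout))),
    numeric(1))
  expect_lt(mean(pre), 0.25)
})

test_that("uncoupled dyads show no excess overlap; follow coupling creates it", {
  n <- 60L
  raw_at <- function(gf) {
    co <- simulate_cohort(sim_config(gamma_follow = gf), n, seed = 31,
                          id_prefix = paste0("g", gf))
    vals <- vapply(co$dyads, function(d)
      raw_synchrony(d, n_surrogates = 150L, seed = 31)$raw, numeric(1))
    vals[!is.na(vals)]
  }
  null_vals <- raw_at(0)
  ci <- stats::t.test(null_vals)$conf.int
  coupled_vals <- raw_at(4)
  expect_gt(mean(coupled_vals), mean(null_vals) + 1)
  expect_gt(stats::t.test(coupled_vals)$conf.int[1], 1)
  # uncoupled raw synchrony is small on average (the non-social component)
  expect_lt(abs(mean(null_vals)), 1.5)
})

test_that("SINGLE configuration removes coupling but keeps the subjects", {
  cfg <- sim_config(gamma_follow = 4, buffering_shift = 0.8)
  dp <- simulate_dyad(cfg, seed = 13, dyad_id = "q1", configuration = "PAIR")
  ds <- simulate_dyad(cfg, seed = 13, dyad_id = "q1", configuration = "SINGLE",
                      subject_effects = attr(dp, "subject_effects"))
  expect_identical(attr(ds, "subject_effects"), attr(dp, "subject_effects"))
  expect_equal(ds$configuration, "SINGLE")
  expect_false(identical(dp$ethogram_a$bouts, ds$ethogram_a$bouts))
})

test_that("playback partners replay the pattern exactly", {
  src <- simulate_dyad(sim_config(), seed = 2, dyad_id = "src")
  pattern <- src$ethogram_b
  pb <- playback_partner(pattern, sim_config(gamma_follow = 3), seed = 5)
  expect_identical(pb$ethogram_b$bouts, pattern$bouts)
  expect_silent(validate_ethogram(pb$ethogram_a))
  other_layout <- session_layout(fps = 5L)
  expect_error(playback_partner(pattern, sim_config(layout = other_layout)),
               "layout")
})

test_that("coupling to a playback pattern mirrors the social-object contrast", {
  src <- simulate_dyad(sim_config(), seed = 2, dyad_id = "src")
  pattern <- src$ethogram_b
  syn_at <- function(gf, n = 40L) {
    vals <- vapply(seq_len(n), function(i) {
      pb <- playback_partner(pattern, sim_config(gamma_follow = gf), seed = 100 + i,
                             dyad_id = sprintf("pb%02d", i))
      raw_synchrony(pb, n_surrogates = 150L, seed = i)$raw
    }, numeric(1))
    vals[!is.na(vals)]
  }
  inert <- syn_at(0)     # clean, non-social object
  social <- syn_at(4)    # socially salient object
  expect_lt(abs(mean(inert)), 1)
  expect_gt(mean(social), mean(inert))
  expect_gt(stats::t.test(social)$conf.int[1], 0)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(on_peak = 1.2), "hazards")
  expect_error(sim_config(gamma_follow = -1), "gamma")
  expect_error(sim_config(buffering_shift = 2), "buffering_shift")
})
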