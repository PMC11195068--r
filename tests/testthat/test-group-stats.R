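test_that("freezing level is the percent of frozen frames", {
  expect_equal(freezing_level(rep(1, 480)), 100)
  expect_equal(freezing_level(rep(0, 480)), 0)
  expect_equal(freezing_level(rep(c(1, 0), 240)), 50)
})

test_that("equalization metrics compare paired absolute freezing differences", {
  pair <- data.frame(dyad_id = c("d1", "d2"), freeze_a = c(80, 50),
                     freeze_b = c(80, 20))
  single <- data.frame(dyad_id = c("d2", "d1"), freeze_a = c(70, 90),
                       freeze_b = c(10, 40))
  eq <- equalization_metrics(pair, single)
  expect_equal(eq$diff_pair, c(0, 30))
  expect_equal(eq$diff_single, c(50, 60))  # matched back to d1, d2 order
  expect_error(
    equalization_metrics(pair, single[single$dyad_id != "d1", ]),
    "missing a SINGLE configuration"
  )
})

test_that("buffering-coupled simulations equalize partners in PAIR", {
  cfg <- sim_config(gamma_follow = 1, buffering_shift = 0.9)
  pair <- list(); single <- list()
  for (i in 1:25) {
    did <- sprintf("d%02d", i)
    dp <- simulate_dyad(cfg, seed = 9, dyad_id = did, configuration = "PAIR")
    ds <- simulate_dyad(cfg, seed = 9, dyad_id = did, configuration = "SINGLE",
                        subject_effects = attr(dp, "subject_effects"))
    row <- function(d) data.frame(
      dyad_id = did,
      freeze_a = freezing_level(bouts_to_trace(d$ethogram_a)),
      freeze_b = freezing_level(bouts_to_trace(d$ethogram_b)))
    pair[[i]] <- row(dp); single[[i]] <- row(ds)
  }
  eq <- equalization_metrics(do.call(rbind, pair), do.call(rbind, single))
  expect_lt(mean(eq$diff_pair), mean(eq$diff_single))
})

test_that("balanced assignment alternates high and low freezers", {
  g <- data.frame(
    dyad_id = sprintf("d%d", 1:5),
    subject_a = sprintf("a%d", 1:5), subject_b = sprintf("b%d", 1:5),
    freeze_a = c(90, 70, 55, 30, 20), freeze_b = c(80, 75, 40, 35, 10)
  )
  asg <- balanced_partner_assignment(g)
  # columns hold near-equal numbers of high freezers (differ by <= 1)
  expect_lte(abs(sum(asg$high_in_1) - sum(!asg$high_in_1)), 1L)
  # on 4 dyads the counts are exactly equal
  asg4 <- balanced_partner_assignment(g[1:4, ])
  expect_equal(sum(asg4$high_in_1), 2L)
  # column means are closer than the worst-case all-high-vs-all-low split
  worst <- abs(mean(pmax(g$freeze_a, g$freeze_b)) -
               mean(pmin(g$freeze_a, g$freeze_b)))
  got <- abs(mean(asg$animal1_freeze) - mean(asg$animal2_freeze))
  expect_lt(got, worst)
  # ties resolved by subject id order with a message
  gt <- g; gt$freeze_b[1] <- gt$freeze_a[1]
  expect_message(balanced_partner_assignment(gt), "tie")
})

test_that("opposite-sex assignment puts the male in column 1", {
  g <- data.frame(
    dyad_id = c("d1", "d2", "d3"),
    subject_a = c("m1", "m2", "m3"), subject_b = c("f1", "f2", "f3"),
    freeze_a = c(10, 50, 80), freeze_b = c(90, 55, 20),
    sex_composition = "MF"
  )
  asg <- balanced_partner_assignment(g)
  expect_setequal(asg$animal1_id, c("m1", "m2", "m3"))
})

test_that("partner correlation behaves on toy data", {
  dup <- data.frame(dyad_id = sprintf("d%d", 1:6),
                    animal1_freeze = c(10, 30, 50, 60, 80, 90))
  dup$animal2_freeze <- dup$animal1_freeze
  expect_equal(partner_correlation(dup)$r, 1)
  anti <- dup; anti$animal2_freeze <- rev(dup$animal1_freeze)
  expect_lt(partner_correlation(anti)$r, 0)
  expect_error(partner_correlation(dup[1:2, ]), "at least 3")
  # independent freezing shows no systematic correlation
  set.seed(5)
  rs <- replicate(200, {
    d <- data.frame(animal1_freeze = stats::runif(10, 0, 100),
                    animal2_freeze = stats::runif(10, 0, 100))
    partner_correlation(d)$r
  })
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("top/bottom split takes floor(fraction N) disjoint dyads", {
  g <- data.frame(dyad_id = sprintf("d%02d", 1:20), corrected = stats::rnorm(20))
  sp <- split_top_bottom(g)
  expect_equal(sp$k, 8L)  # floor(0.4 * 20)
  expect_equal(nrow(sp$top), 8L)
  expect_equal(nrow(sp$bottom), 8L)
  expect_length(intersect(sp$top$dyad_id, sp$bottom$dyad_id), 0L)
  expect_true(min(sp$top$corrected) >= max(sp$bottom$corrected))
  expect_equal(split_top_bottom(g[1:5, ])$k, 2L)
  # all-equal key: deterministic id-ordered split with a warning
  ge <- data.frame(dyad_id = sprintf("d%02d", 1:5), corrected = 1)
  expect_warning(spe <- split_top_bottom(ge), "ties")
  expect_equal(spe$bottom$dyad_id, c("d01", "d02"))
  expect_error(split_top_bottom(g[1:2, ]), "too small")
})

test_that("synchrony-behavior correlation is Pearson with two-tailed p", {
  g <- data.frame(dyad_id = sprintf("d%d", 1:8),
                  corrected = c(0.2, 0.5, 1.1, 1.4, 2.0, 2.2, 3.0, 3.3))
  g$follow_total <- g$corrected  # identical -> r = 1
  expect_equal(synchrony_behavior_correlation(g, "follow_total")$r, 1)
  g$r2m <- -2 * g$corrected + stats::rnorm(8, sd = 1e-6)
  expect_lt(synchrony_behavior_correlation(g, "r2m")$r, -0.99)
})
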