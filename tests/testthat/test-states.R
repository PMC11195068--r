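test_that("dyad state encoding maps trace pairs to states 0-3", {
  s <- dyad_state_sequence(c(1, 1, 0), c(1, 0, 0))
  expect_equal(s$states, c(0L, 1L, 3L))
  expect_equal(s$collapsed, c(0L, 1L, 3L))
  expect_equal(dyad_state_sequence(rep(1, 5), rep(1, 5))$collapsed, 0L)
  s2 <- dyad_state_sequence(c(1, 1, 1, 1), c(0, 0, 1, 1))
  expect_equal(s2$states, c(1L, 1L, 0L, 0L))
  expect_equal(s2$collapsed, c(1L, 0L))
})

test_that("state encoding is invertible back to the trace pair", {
  set.seed(3)
  for (rep in 1:20) {
    a <- sample(0:1, 50, replace = TRUE)
    b <- sample(0:1, 50, replace = TRUE)
    st <- dyad_state_sequence(a, b)$states
    expect_equal(1L - st %/% 2L, a)
    expect_equal(1L - st %% 2L, b)
  }
})

test_that("transition matrix has 16 cells and conserves frame count", {
  m <- transition_counts(c(0L, 0L, 1L, 0L))
  expect_equal(dim(m), c(4L, 4L))
  expect_equal(m["0", "0"], 1L)
  expect_equal(m["0", "1"], 1L)
  expect_equal(m["1", "0"], 1L)
  expect_equal(sum(m), 3L)
  # constant sequence: one self-loop cell holds frames - 1
  mc <- transition_counts(rep(2L, 480))
  expect_equal(mc["2", "2"], 479L)
  expect_equal(sum(mc) - sum(diag(mc)), 0L)
  # conservation on random sequences; collapsed length tracks off-diagonal moves
  set.seed(9)
  for (rep in 1:10) {
    st <- sample(0:3, 200, replace = TRUE)
    mm <- transition_counts(st)
    expect_equal(sum(mm), 199L)
    expect_equal(length(rle(st)$values), 1L + sum(mm) - sum(diag(mm)))
  }
})

test_that("follow counting matches the motif definition", {
  f <- count_follow(c(3L, 1L, 0L, 2L, 3L))
  expect_equal(unname(f), c(1L, 1L, 2L), ignore_attr = TRUE)
  expect_equal(unname(count_follow(0L)), c(0L, 0L, 0L), ignore_attr = TRUE)
  # direct congruent-congruent switches count as follows and are flagged
  fd <- count_follow(c(0L, 3L, 0L))
  expect_equal(unname(fd), c(1L, 1L, 2L), ignore_attr = TRUE)
  expect_equal(attr(fd, "n_direct"), 2L)
  # an excursion through both incongruent states counts as nothing (strict)
  expect_equal(unname(count_follow(c(0L, 1L, 2L, 3L))), c(0L, 0L, 0L), ignore_attr = TRUE)
  expect_equal(unname(count_follow(c(0L, 1L, 2L, 3L), mode = "lenient")),
               c(0L, 1L, 1L), ignore_attr = TRUE)
})

test_that("retroact counting matches the loop definition", {
  expect_equal(unname(count_retroact(c(0L, 1L, 0L, 1L, 0L))), c(2L, 0L))
  expect_equal(unname(count_retroact(c(3L, 2L, 3L))), c(0L, 1L))
  expect_equal(unname(count_retroact(c(0L, 1L, 3L, 2L, 0L))), c(0L, 0L))
  # lenient mode accepts multi-state incongruent excursions that return
  expect_equal(unname(count_retroact(c(0L, 1L, 2L, 0L), mode = "lenient")),
               c(1L, 0L))
  expect_equal(unname(count_retroact(c(0L, 1L, 2L, 0L))), c(0L, 0L))
})

test_that("counts on per-frame sequences ignore within-state dwell", {
  # dwell frames inside states must not break motifs
  a <- c(1, 1, 1, 0, 0, 1, 1, 1, 1)  # freeze, break, refreeze
  b <- rep(1, 9)
  s <- dyad_state_sequence(a, b)
  expect_equal(s$collapsed, c(0L, 2L, 0L))  # A (trace 1) breaks -> state 2
  expect_equal(unname(count_retroact(s)), c(1L, 0L))
  expect_equal(unname(count_follow(s)), c(0L, 0L, 0L), ignore_attr = TRUE)
})

test_that("follow/retroact agree with the brute-force scanner", {
  set.seed(101)
  for (rep in 1:300) {
    cc <- random_collapsed(sample(2:40, 1L))
    f <- count_follow(cc)
    bf <- brute_follow(cc)
    expect_identical(unname(f[1:2]), unname(bf))
    r <- count_retroact(cc)
    br <- brute_retroact(cc)
    expect_identical(unname(r), unname(br))
  }
})

test_that("behavior_counts assembles one record per dyad", {
  s <- dyad_state_sequence(c(1, 1, 0, 0, 1, 1, 1, 1), c(1, 0, 0, 1, 1, 0, 0, 1))
  bc <- behavior_counts(s, dyad_id = "d1")
  expect_named(bc, c("dyad_id", "f2f", "f2m", "follow_total", "r2f", "r2m",
                     "n_direct"))
  expect_equal(bc$follow_total, bc$f2f + bc$f2m)
  expect_identical(unname(unlist(bc[c("f2f", "f2m")])),
                   as.integer(brute_follow(s$collapsed)))
})
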