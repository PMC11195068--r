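# Independent brute-force oracles used to validate the counting and null
# machinery. Deliberately written as naive pattern scans / enumerations,
# structurally different from the package implementations.

# Slide a window over the collapsed sequence and match motif patterns
# literally: congruent -> single incongruent -> other congruent, or a direct
# congruent -> other congruent adjacency.
brute_follow <- function(collapsed) {
  n <- length(collapsed)
  f2f <- 0L; f2m <- 0L
  for (i in seq_len(n)) {
    trip <- if (i + 2L <= n) collapsed[i:(i + 2L)] else NULL
    pair <- if (i + 1L <= n) collapsed[i:(i + 1L)] else NULL
    if (!is.null(trip)) {
      if (identical(trip[c(1, 3)], c(3L, 0L)) && trip[2] %in% c(1L, 2L)) f2f <- f2f + 1L
      if (identical(trip[c(1, 3)], c(0L, 3L)) && trip[2] %in% c(1L, 2L)) f2m <- f2m + 1L
    }
    if (!is.null(pair)) {
      if (identical(pair, c(3L, 0L))) f2f <- f2f + 1L
      if (identical(pair, c(0L, 3L))) f2m <- f2m + 1L
    }
  }
  c(f2f = f2f, f2m = f2m)
}

brute_retroact <- function(collapsed) {
  n <- length(collapsed)
  r2f <- 0L; r2m <- 0L
  for (i in seq_len(max(0L, n - 2L))) {
    trip <- collapsed[i:(i + 2L)]
    if (trip[1] == 0L && trip[2] %in% c(1L, 2L) && trip[3] == 0L) r2f <- r2f + 1L
    if (trip[1] == 3L && trip[2] %in% c(1L, 2L) && trip[3] == 3L) r2m <- r2m + 1L
  }
  c(r2f = r2f, r2m = r2m)
}

# Exhaustive circular-rotation overlap distribution via explicit modular
# indexing (the package uses a doubled-vector slice instead).
rotation_overlaps <- function(a, b) {
  n <- length(a)
  vapply(seq_len(n - 1L), function(k) {
    rotated <- b[((seq_len(n) - 1L + k) %% n) + 1L]
    mean(a * rotated)
  }, numeric(1))
}

# Random collapsed state sequence: consecutive entries always differ.
random_collapsed <- function(len) {
  s <- integer(len)
  s[1] <- sample(0:3, 1L)
  for (i in seq_len(len - 1L)) {
    s[i + 1L] <- sample(setdiff(0:3, s[i]), 1L)
  }
  s
}

# Random collapsed sequence with no direct 0<->3 and no direct 1<->2
# adjacency: every step crosses between the congruent {0,3} and
# incongruent {1,2} tiers.
random_collapsed_no_double_switch <- function(len) {
  s <- integer(len)
  s[1] <- sample(0:3, 1L)
  for (i in seq_len(len - 1L)) {
    allowed <- if (s[i] %in% c(0L, 3L)) c(1L, 2L) else c(0L, 3L)
    s[i + 1L] <- sample(allowed, 1L)
  }
  s
}

# Random 0/1 trace with bout-like runs (freezing runs of >= 4 frames),
# guaranteed non-degenerate.
bout_like_trace <- function(n) {
  repeat {
    x <- integer(0)
    state <- sample(0:1, 1L)
    while (length(x) < n) {
      len <- if (state == 1L) sample(4:12, 1L) else sample(1:8, 1L)
      x <- c(x, rep(state, len))
      state <- 1L - state
    }
    x <- x[seq_len(n)]
    if (mean(x) > 0 && mean(x) < 1) return(x)
  }
}

# Build a tiny valid ethogram collection quickly: k dyads (2k subjects),
# each subject with one distinct CS bout, for enumeration tests.
toy_real_dyads <- function(k, sex_composition = "MM", layout = session_layout()) {
  lapply(seq_len(k), function(i) {
    s <- layout$cs_start
    a <- ethogram(sprintf("s%03da", i), data.frame(start = s, end = s + 8L), layout)
    b <- ethogram(sprintf("s%03db", i), data.frame(start = s + 12L, end = s + 20L), layout)
    dyad(sprintf("d%03d", i), a, b, sex_composition = sex_composition)
  })
}
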