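#' Observed freezing overlap of two traces
#'
#' Fraction of analysis-window frames in which both animals freeze
#' simultaneously.
#'
#' @param trace_a,trace_b Equal-length 0/1 vectors (see [bouts_to_trace()]).
#' @return A fraction in `[0, min(p_a, p_b)]`.
#' @export
observed_overlap <- function(trace_a, trace_b) {
  check_traces(trace_a, trace_b)
  mean(trace_a == 1L & trace_b == 1L)
}

#' Chance freezing overlap under independence
#'
#' The overlap expected if the two animals froze independently with their
#' observed freezing fractions: `p_a * p_b`.
#'
#' @inheritParams observed_overlap
#' @return A fraction.
#' @export
chance_overlap <- function(trace_a, trace_b) {
  check_traces(trace_a, trace_b)
  mean(trace_a) * mean(trace_b)
}

check_traces <- function(trace_a, trace_b) {
  if (length(trace_a) != length(trace_b)) {
    stop("traces must have equal length (got ", length(trace_a), " and ",
         length(trace_b), ")")
  }
  if (length(trace_a) == 0L) stop("traces must be non-empty")
  invisible(NULL)
}

#' Null spread of the freezing overlap
#'
#' Standard deviation of the overlap statistic under a no-coupling null,
#' used as the denominator when standardizing the observed-minus-chance
#' overlap. Two nulls are provided:
#'
#' * `"circular_shift"` (default): overlap of `trace_a` against circular
#'   rotations of `trace_b`. Rotation preserves each animal's bout and
#'   autocorrelation structure — the appropriate null for strongly
#'   autocorrelated freezing traces. When `n_surrogates` is at least the
#'   number of distinct nonzero rotations, all rotations are enumerated
#'   exactly (deterministic); otherwise rotations are sampled with the given
#'   seed.
#' * `"binomial"`: closed form `sqrt(E (1 - E) / n)` treating frames as
#'   independent Bernoulli draws; fast but anticonservative for bouts longer
#'   than one frame.
#'
#' @inheritParams observed_overlap
#' @param method `"circular_shift"` or `"binomial"`.
#' @param n_surrogates Number of surrogate rotations (>= 100) for the
#'   circular-shift null.
#' @param seed Integer seed for surrogate sampling (ignored when exhaustive
#'   or binomial).
#' @return The null standard deviation (positive scalar), with attribute
#'   `null_mean` (mean surrogate overlap; equals the chance overlap exactly
#'   under exhaustive rotation). Returns `NA` with a warning for degenerate
#'   traces (an animal freezing in no frame or every frame).
#' @export
null_overlap_spread <- function(trace_a, trace_b,
                                method = c("circular_shift", "binomial"),
                                n_surrogates = 1000L, seed = 1L) {
  method <- match.arg(method)
  check_traces(trace_a, trace_b)
  n <- length(trace_a)
  p_a <- mean(trace_a)
  p_b <- mean(trace_b)
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) {
    warning("degenerate trace (freezing fraction 0 or 1); null spread undefined")
    return(NA_real_)
  }
  if (method == "binomial") {
    e <- p_a * p_b
    out <- sqrt(e * (1 - e) / n)
    attr(out, "null_mean") <- e
    return(out)
  }
  if (n_surrogates < 100L) stop("circular_shift null needs n_surrogates >= 100")
  ks <- if (n_surrogates >= n - 1L) {
    seq_len(n - 1L)  # exhaustive: every nonzero rotation once
  } else {
    set.seed(as.integer(seed %% .Machine$integer.max))
    sample.int(n - 1L, n_surrogates, replace = TRUE)
  }
  bb <- c(trace_b, trace_b)
  overlaps <- vapply(ks, function(k) {
    sum(trace_a * bb[(k + 1L):(k + n)]) / n
  }, numeric(1))
  # population SD over the enumerated/sampled null ensemble
  m <- mean(overlaps)
  out <- sqrt(mean((overlaps - m)^2))
  attr(out, "null_mean") <- m
  out
}

#' Standardized (raw) fear synchrony of one dyad
#'
#' The standardized difference between observed and chance freezing overlap
#' over the analysis window:
#' `S_raw = (O - E) / null_sd`. Positive values mean the animals froze
#' together more than expected by chance; the score is not yet corrected for
#' the group's non-social component (see [corrected_synchrony()]).
#'
#' @param dyad A [dyad()] object, or `trace_a` may be given directly.
#' @param trace_a,trace_b Alternatively, two equal-length 0/1 traces.
#' @inheritParams null_overlap_spread
#' @param window Analysis window passed to [bouts_to_trace()] when a dyad is
#'   given; defaults to the CS segment.
#' @return A one-row data frame: `dyad_id`, `p_a`, `p_b`, `observed`,
#'   `chance`, `null_sd`, `raw`. Degenerate dyads get `NA` synchrony and a
#'   warning; they should be excluded downstream.
#' @export
raw_synchrony <- function(dyad = NULL, trace_a = NULL, trace_b = NULL,
                          method = c("circular_shift", "binomial"),
                          n_surrogates = 1000L, seed = 1L, window = NULL) {
  method <- match.arg(method)
  dyad_id <- NA_character_
  if (!is.null(dyad)) {
    stopifnot(inherits(dyad, "dyad"))
    dyad_id <- dyad$dyad_id
    trace_a <- bouts_to_trace(dyad$ethogram_a, window)
    trace_b <- bouts_to_trace(dyad$ethogram_b, window)
    seed <- derive_seed(seed, dyad$dyad_id)
  }
  check_traces(trace_a, trace_b)
  p_a <- mean(trace_a)
  p_b <- mean(trace_b)
  o <- observed_overlap(trace_a, trace_b)
  e <- chance_overlap(trace_a, trace_b)
  sd0 <- if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) {
    warning(sprintf("dyad %s: degenerate trace (p_a=%.2f, p_b=%.2f); synchrony undefined",
                    dyad_id, p_a, p_b))
    NA_real_
  } else {
    null_overlap_spread(trace_a, trace_b, method = method,
                        n_surrogates = n_surrogates, seed = seed)
  }
  sd0 <- as.numeric(sd0)
  data.frame(
    dyad_id = dyad_id, p_a = p_a, p_b = p_b,
    observed = o, chance = e, null_sd = sd0,
    raw = if (is.na(sd0)) NA_real_ else (o - e) / sd0
  )
}

#' Sliding-window freezing-probability trace of a cohort
#'
#' Per-subject centered moving average of the binary freezing trace (window
#' of `window_s` seconds), then the across-subject mean and SD per frame —
#' the "averaged freezing probability" curve used to visualise the rapid
#' post-CS-onset rise and slow decline of freezing.
#'
#' @param traces A list of equal-length 0/1 traces (one per subject).
#' @param fps Frames per second (taken from the first trace's attribute if
#'   absent).
#' @param window_s Smoothing window in seconds (default 1).
#' @return A data frame with columns `frame` (0-based, within the window),
#'   `time_s`, `mean`, `sd`, plus per-frame `n`.
#' @export
freezing_probability_trace <- function(traces, fps = NULL, window_s = 1) {
  if (!length(traces)) stop("`traces` must be a non-empty list")
  if (is.null(fps)) fps <- attr(traces[[1]], "fps")
  if (is.null(fps)) stop("`fps` not given and not found on the first trace")
  n <- length(traces[[1]])
  if (!all(vapply(traces, length, integer(1)) == n)) {
    stop("all traces must have equal length")
  }
  w <- max(1L, as.integer(round(fps * window_s)))
  smooth_one <- function(x) {
    # centered moving average with edge shrinkage (partial windows at ends)
    cs <- cumsum(c(0, x))
    half_lo <- (w - 1L) %/% 2L
    half_hi <- w %/% 2L
    idx <- seq_len(n)
    lo <- pmax(idx - half_lo, 1L)
    hi <- pmin(idx + half_hi, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  mat <- vapply(traces, smooth_one, numeric(n))
  data.frame(
    frame = seq_len(n) - 1L,
    time_s = (seq_len(n) - 1L) / fps,
    mean = rowMeans(mat),
    sd = apply(mat, 1L, stats::sd),
    n = length(traces)
  )
}
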