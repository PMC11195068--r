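#' A dyad of ethograms
#'
#' Pairs two subjects' ethograms with the metadata the group-level analyses
#' need. For opposite-sex (`"MF"`) dyads, member `a` is the male and member
#' `b` the female by convention.
#'
#' @param dyad_id Dyad identifier.
#' @param ethogram_a,ethogram_b [ethogram()] objects sharing one layout.
#' @param sex_composition `"MM"`, `"FF"` or `"MF"`.
#' @param familiarity `"familiar"` or `"unfamiliar"`.
#' @param treatment Free-text treatment label (e.g. `"control"`, `"stress"`).
#' @param group Experimental-group label used for the virtual-dyad
#'   correction; defaults to `sex_composition`.
#' @param configuration `"PAIR"` (tested together) or `"SINGLE"` (tested in
#'   separate chambers).
#' @param is_virtual TRUE for virtual dyads assembled from subjects that were
#'   never tested together.
#' @return An object of class `dyad`.
#' @export
dyad <- function(dyad_id, ethogram_a, ethogram_b,
                 sex_composition = c("MM", "FF", "MF"),
                 familiarity = "familiar", treatment = "control",
                 group = NULL, configuration = "PAIR", is_virtual = FALSE) {
  sex_composition <- match.arg(sex_composition)
  stopifnot(inherits(ethogram_a, "ethogram"), inherits(ethogram_b, "ethogram"))
  if (identical(ethogram_a$subject_id, ethogram_b$subject_id)) {
    stop("a dyad needs two distinct subjects")
  }
  if (!identical(unclass(ethogram_a$layout), unclass(ethogram_b$layout))) {
    stop("both ethograms must share the same session layout")
  }
  structure(
    list(
      dyad_id = as.character(dyad_id),
      ethogram_a = ethogram_a, ethogram_b = ethogram_b,
      sex_composition = sex_composition,
      sex_a = if (sex_composition == "FF") "F" else "M",
      sex_b = if (sex_composition == "MM") "M" else "F",
      familiarity = familiarity, treatment = treatment,
      group = if (is.null(group)) sex_composition else as.character(group),
      configuration = configuration,
      is_virtual = isTRUE(is_virtual)
    ),
    class = "dyad"
  )
}

#' @export
print.dyad <- function(x, ...) {
  cat(sprintf("<dyad> %s: %s + %s [%s, %s, %s%s]\n", x$dyad_id,
              x$ethogram_a$subject_id, x$ethogram_b$subject_id,
              x$sex_composition, x$familiarity, x$treatment,
              if (x$is_virtual) ", virtual" else ""))
  invisible(x)
}

#' Enumerate the virtual dyads of an experimental group
#'
#' Virtual dyads pair subjects of one group that were never actually tested
#' together; their synchrony estimates the non-social component that similar
#' CS-locked freezing dynamics alone produce. For same-sex groups every
#' unordered subject pair except the real pairs is formed — `k` real dyads
#' (2k subjects) yield `choose(2k, 2) - k` virtual dyads (20 real dyads give
#' 760, 23 give 1012). For opposite-sex groups only male-female cross pairs
#' are conceivable dyads, giving `k^2 - k`.
#'
#' @param real_dyads A list of real [dyad()]s from one group (>= 2).
#' @return A list of virtual `dyad` objects inheriting the group's labels,
#'   with ids `v_<subjectA>_<subjectB>`.
#' @export
enumerate_virtual_dyads <- function(real_dyads) {
  if (length(real_dyads) < 2L) stop("need at least 2 real dyads")
  stopifnot(all(vapply(real_dyads, inherits, logical(1), "dyad")))
  proto <- real_dyads[[1]]
  members <- do.call(rbind, lapply(real_dyads, function(d) {
    data.frame(subject_id = c(d$ethogram_a$subject_id, d$ethogram_b$subject_id),
               sex = c(d$sex_a, d$sex_b), stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(members$subject_id)) {
    stop("duplicate subject ids across real dyads: ",
         paste(unique(members$subject_id[duplicated(members$subject_id)]), collapse = ", "))
  }
  eths <- stats::setNames(
    do.call(c, lapply(real_dyads, function(d) list(d$ethogram_a, d$ethogram_b))),
    members$subject_id
  )
  real_keys <- vapply(real_dyads, function(d) {
    paste(sort(c(d$ethogram_a$subject_id, d$ethogram_b$subject_id)), collapse = "\r")
  }, character(1))
  pairs <- if (proto$sex_composition == "MF") {
    males <- members$subject_id[members$sex == "M"]
    females <- members$subject_id[members$sex == "F"]
    expand.grid(a = males, b = females, stringsAsFactors = FALSE)
  } else {
    cmb <- utils::combn(members$subject_id, 2L)
    data.frame(a = cmb[1L, ], b = cmb[2L, ], stringsAsFactors = FALSE)
  }
  keys <- vapply(seq_len(nrow(pairs)), function(i) {
    paste(sort(c(pairs$a[i], pairs$b[i])), collapse = "\r")
  }, character(1))
  pairs <- pairs[!keys %in% real_keys, , drop = FALSE]
  lapply(seq_len(nrow(pairs)), function(i) {
    dyad(sprintf("v_%s_%s", pairs$a[i], pairs$b[i]),
         eths[[pairs$a[i]]], eths[[pairs$b[i]]],
         sex_composition = proto$sex_composition,
         familiarity = proto$familiarity, treatment = proto$treatment,
         group = proto$group, configuration = proto$configuration,
         is_virtual = TRUE)
  })
}

#' Subtract the group's non-social synchrony component
#'
#' The corrected synchrony of a dyad is its raw standardized synchrony minus
#' the mean raw synchrony of the group's virtual dyads — the non-social
#' component contributed by shared CS-locked freezing dynamics alone. By
#' construction the mean corrected synchrony of the virtual dyads is zero.
#'
#' @param real_results Data frame of [raw_synchrony()] rows for real dyads.
#' @param virtual_results The same for the group's virtual dyads (non-empty).
#' @return `real_results` with a `corrected` column appended and the
#'   subtracted constant in attribute `nonsocial_component`.
#' @export
corrected_synchrony <- function(real_results, virtual_results) {
  if (is.null(virtual_results) || nrow(virtual_results) == 0L) {
    stop("virtual dyad results are empty; cannot estimate the non-social component")
  }
  nonsocial <- mean(virtual_results$raw, na.rm = TRUE)
  out <- real_results
  out$corrected <- out$raw - nonsocial
  attr(out, "nonsocial_component") <- nonsocial
  out
}

#' Full synchrony analysis of one experimental group
#'
#' Computes raw synchrony for every real dyad and every virtual dyad of the
#' group, then applies the virtual-dyad correction.
#'
#' @param real_dyads List of real [dyad()]s of one group.
#' @param virtual_dyads Optional pre-built virtual dyads; enumerated from
#'   `real_dyads` when NULL.
#' @inheritParams raw_synchrony
#' @param seed Pipeline-level seed; fanned out per dyad id so results do not
#'   depend on iteration order.
#' @return A list with `real` (corrected results, one row per non-degenerate
#'   real dyad), `virtual` (virtual-dyad results), and `nonsocial_component`.
#' @export
group_synchrony <- function(real_dyads, virtual_dyads = NULL,
                            method = c("circular_shift", "binomial"),
                            n_surrogates = 1000L, seed = 1L, window = NULL) {
  method <- match.arg(method)
  if (is.null(virtual_dyads)) virtual_dyads <- enumerate_virtual_dyads(real_dyads)
  run <- function(dyads) {
    rows <- lapply(dyads, raw_synchrony, method = method,
                   n_surrogates = n_surrogates, seed = seed, window = window)
    do.call(rbind, rows)
  }
  real_res <- run(real_dyads)
  virt_res <- run(virtual_dyads)
  degenerate <- is.na(virt_res$raw)
  if (any(degenerate)) virt_res <- virt_res[!degenerate, , drop = FALSE]
  real_corr <- corrected_synchrony(real_res, virt_res)
  list(
    real = real_corr,
    virtual = virt_res,
    nonsocial_component = attr(real_corr, "nonsocial_component")
  )
}

#' Deterministic per-key seed derivation
#'
#' Fans a single pipeline seed out into independent, reproducible
#' sub-seeds keyed by strings (dyad ids, operation names), so per-dyad
#' randomness does not depend on the order dyads are processed in.
#'
#' @param seed Integer master seed.
#' @param key Character key.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, key) {
  m <- 2147483647  # 2^31 - 1 (Mersenne prime, Lehmer modulus)
  h <- 7
  for (code in utf8ToInt(paste(key, collapse = "|"))) {
    h <- (h * 31 + code) %% m
  }
  as.integer(((as.numeric(seed) %% m) * 48271 + h) %% (m - 1) + 1)
}
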