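#' Freezing level of a trace
#'
#' Percentage of analysis-window frames spent freezing.
#'
#' @param trace 0/1 freezing trace.
#' @return Percent in `[0, 100]`.
#' @export
freezing_level <- function(trace) {
  100 * mean(as.integer(trace))
}

#' Freezing equalization between partners
#'
#' For each dyad, the absolute difference between the two partners' freezing
#' levels when tested together (PAIR) and when tested in separate chambers
#' (SINGLE). Social cues equalize fear levels, so PAIR differences are
#' expected to be stochastically smaller; the paired comparison is delegated
#' to the Wilcoxon matched-pairs test.
#'
#' @param pair_table,single_table Data frames with columns `dyad_id`,
#'   `freeze_a`, `freeze_b` (freezing percentages per member) for the two
#'   configurations; every dyad must appear in both.
#' @return Data frame `dyad_id`, `diff_pair`, `diff_single`, with the paired
#'   `stats::wilcox.test` result in attribute `test`.
#' @export
equalization_metrics <- function(pair_table, single_table) {
  need <- c("dyad_id", "freeze_a", "freeze_b")
  stopifnot(all(need %in% names(pair_table)), all(need %in% names(single_table)))
  missing <- setdiff(pair_table$dyad_id, single_table$dyad_id)
  if (length(missing)) {
    stop("dyads missing a SINGLE configuration: ", paste(missing, collapse = ", "))
  }
  single_table <- single_table[match(pair_table$dyad_id, single_table$dyad_id), ]
  out <- data.frame(
    dyad_id = pair_table$dyad_id,
    diff_pair = abs(pair_table$freeze_a - pair_table$freeze_b),
    diff_single = abs(single_table$freeze_a - single_table$freeze_b)
  )
  if (nrow(out) >= 3L) {
    attr(out, "test") <- stats::wilcox.test(out$diff_pair, out$diff_single,
                                            paired = TRUE, exact = FALSE)
  }
  out
}

#' Balanced assignment of partners for correlation analysis
#'
#' Correlating "animal 1" against "animal 2" freezing across dyads is
#' spurious if one column systematically holds the higher freezer. The
#' balanced scheme sorts dyads by mean freezing (descending), identifies the
#' higher and lower freezer within each dyad, and alternates which column
#' receives the high freezer, moving from the highest-mean dyad to the
#' lowest. The two columns end up with equal numbers (within 1) of high and
#' low freezers and near-equal means. For opposite-sex groups the assignment
#' is fixed instead: male to column 1, female to column 2.
#'
#' @param group Data frame with columns `dyad_id`, `subject_a`, `subject_b`,
#'   `freeze_a`, `freeze_b`, and optionally `sex_composition`.
#' @param opposite_sex If TRUE (or if `sex_composition` is `"MF"` for all
#'   rows), use the fixed male/female assignment; member `a` is the male.
#' @return Data frame `dyad_id`, `animal1_id`, `animal1_freeze`,
#'   `animal2_id`, `animal2_freeze`, `high_in_1` (logical), sorted by mean
#'   freezing descending.
#' @export
balanced_partner_assignment <- function(group, opposite_sex = NULL) {
  need <- c("dyad_id", "subject_a", "subject_b", "freeze_a", "freeze_b")
  stopifnot(all(need %in% names(group)))
  if (is.null(opposite_sex)) {
    opposite_sex <- "sex_composition" %in% names(group) &&
      all(group$sex_composition == "MF")
  }
  g <- group[order(-(group$freeze_a + group$freeze_b) / 2, group$dyad_id), ]
  if (opposite_sex) {
    return(data.frame(
      dyad_id = g$dyad_id,
      animal1_id = g$subject_a, animal1_freeze = g$freeze_a,
      animal2_id = g$subject_b, animal2_freeze = g$freeze_b,
      high_in_1 = g$freeze_a >= g$freeze_b
    ))
  }
  n <- nrow(g)
  a1_id <- character(n); a1_fr <- numeric(n)
  a2_id <- character(n); a2_fr <- numeric(n)
  high1 <- logical(n)
  for (i in seq_len(n)) {
    tie <- g$freeze_a[i] == g$freeze_b[i]
    if (tie) {
      message(sprintf("dyad %s: within-dyad freezing tie; using subject-id order",
                      g$dyad_id[i]))
    }
    a_high <- if (tie) g$subject_a[i] <= g$subject_b[i] else g$freeze_a[i] > g$freeze_b[i]
    hi_id <- if (a_high) g$subject_a[i] else g$subject_b[i]
    hi_fr <- if (a_high) g$freeze_a[i] else g$freeze_b[i]
    lo_id <- if (a_high) g$subject_b[i] else g$subject_a[i]
    lo_fr <- if (a_high) g$freeze_b[i] else g$freeze_a[i]
    high1[i] <- i %% 2L == 1L  # odd-ranked dyads put the high freezer in column 1
    if (high1[i]) {
      a1_id[i] <- hi_id; a1_fr[i] <- hi_fr; a2_id[i] <- lo_id; a2_fr[i] <- lo_fr
    } else {
      a1_id[i] <- lo_id; a1_fr[i] <- lo_fr; a2_id[i] <- hi_id; a2_fr[i] <- hi_fr
    }
  }
  data.frame(
    dyad_id = g$dyad_id,
    animal1_id = a1_id, animal1_freeze = a1_fr,
    animal2_id = a2_id, animal2_freeze = a2_fr,
    high_in_1 = high1
  )
}

#' Correlation between partners' freezing levels
#'
#' @param assignment Output of [balanced_partner_assignment()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A one-row data frame `r`, `p`, `n`, `method` (two-tailed p).
#' @export
partner_correlation <- function(assignment, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (nrow(assignment) < 3L) stop("need at least 3 dyads for a correlation")
  x <- assignment$animal1_freeze
  y <- assignment$animal2_freeze
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("degenerate variance in a column")
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  data.frame(r = unname(ct$estimate), p = ct$p.value, n = nrow(assignment),
             method = method)
}

#' Split a group into top and bottom fractions by a ranking key
#'
#' Returns the `floor(fraction * N)` dyads with the highest and lowest key
#' values (default: corrected synchrony); the middle is excluded. Ties at a
#' boundary are broken by dyad id with a warning.
#'
#' @param group Data frame with a `dyad_id` column and the key column.
#' @param fraction Fraction per subset (default 0.40).
#' @param key Name of the ranking column (default `"corrected"`).
#' @return List with `top` and `bottom` data frames (disjoint, each of size
#'   `floor(fraction * N)`) and `k`, the subset size.
#' @export
split_top_bottom <- function(group, fraction = 0.40, key = "corrected") {
  stopifnot("dyad_id" %in% names(group), key %in% names(group))
  n <- nrow(group)
  k <- floor(fraction * n)
  if (k < 1L) stop("group too small for a non-empty ", fraction * 100, "% split")
  v <- group[[key]]
  if (anyDuplicated(v)) {
    ranked <- group[order(v, group$dyad_id), ]
    if (any(duplicated(v)[duplicated(v) %in% TRUE])) {
      warning("ties in ranking key; boundary ties broken by dyad id")
    }
  } else {
    ranked <- group[order(v, group$dyad_id), ]
  }
  list(
    bottom = ranked[seq_len(k), , drop = FALSE],
    top = ranked[seq.int(n - k + 1L, n), , drop = FALSE],
    k = k
  )
}

#' Correlation between synchrony and a behavior count
#'
#' @param group Data frame holding the synchrony column and the behavior
#'   column (one row per dyad).
#' @param behavior Name of the behavior-count column (e.g. `"follow_total"`,
#'   `"r2f"`, `"r2m"`).
#' @param key Name of the synchrony column (default `"corrected"`).
#' @inheritParams partner_correlation
#' @return A one-row data frame `behavior`, `r`, `p`, `n`, `method`.
#' @export
synchrony_behavior_correlation <- function(group, behavior, key = "corrected",
                                           method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(behavior %in% names(group), key %in% names(group))
  ok <- stats::complete.cases(group[[key]], group[[behavior]])
  x <- group[[key]][ok]
  y <- group[[behavior]][ok]
  if (length(x) < 3L) stop("need at least 3 dyads with both values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("degenerate variance")
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  data.frame(behavior = behavior, r = unname(ct$estimate), p = ct$p.value,
             n = length(x), method = method)
}
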