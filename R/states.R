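#' Four-state dyad sequence
#'
#' Collapses a pair of binary freezing traces into the per-frame dyad state:
#' state 0 = both freeze, 1 = A freezes & B moves, 2 = A moves & B freezes,
#' 3 = both move. States 0 and 3 are "congruent" (same action), 1 and 2
#' "incongruent". The run-length-collapsed sequence (consecutive duplicates
#' merged) is the substrate for motif counting.
#'
#' @inheritParams observed_overlap
#' @return An object of class `dyad_states`: list with `states` (per-frame
#'   integer vector in 0..3) and `collapsed` (run-collapsed states).
#' @examples
#' s <- dyad_state_sequence(c(1, 1, 0), c(1, 0, 0))
#' s$states     # 0 1 3
#' @export
dyad_state_sequence <- function(trace_a, trace_b) {
  check_traces(trace_a, trace_b)
  states <- 2L * (1L - as.integer(trace_a)) + (1L - as.integer(trace_b))
  collapsed <- rle(states)$values
  structure(list(states = states, collapsed = collapsed), class = "dyad_states")
}

#' @export
print.dyad_states <- function(x, ...) {
  cat(sprintf("<dyad_states> %d frames, %d collapsed states\n",
              length(x$states), length(x$collapsed)))
  invisible(x)
}

#' Frame-to-frame transition counts
#'
#' Tallies the 16 possible transitions (including the four self-loops) over
#' consecutive frames of the un-collapsed state sequence. The matrix total is
#' always `frames - 1`.
#'
#' @param seq A `dyad_states` object or an integer state vector (0..3).
#' @return A 4x4 integer matrix with dimnames `from`/`to` in "0".."3".
#' @export
transition_counts <- function(seq) {
  states <- if (inherits(seq, "dyad_states")) seq$states else as.integer(seq)
  if (!length(states)) stop("state sequence is empty")
  lv <- as.character(0:3)
  if (length(states) == 1L) {
    m <- matrix(0L, 4L, 4L, dimnames = list(from = lv, to = lv))
    return(m)
  }
  tab <- table(factor(states[-length(states)], levels = 0:3),
               factor(states[-1L], levels = 0:3))
  m <- matrix(as.integer(tab), 4L, 4L, dimnames = list(from = lv, to = lv))
  m
}

collapsed_of <- function(seq) {
  if (inherits(seq, "dyad_states")) seq$collapsed else rle(as.integer(seq))$values
}

#' Count "follow" behaviors
#'
#' A follow event is a transition between the two congruent states (0, both
#' freezing; 3, both moving) either directly or via a single incongruent
#' state (1 or 2) — one mouse changes its freezing state and the partner
#' copies it. Events ending in state 0 are follow-to-freeze; events ending in
#' state 3 are follow-to-move. Counting scans the run-length-collapsed
#' sequence so that dwell frames inside a state never break a motif; each
#' qualifying start index is counted once, and overlapping events may share
#' their endpoint states.
#'
#' Direct 0-3 adjacencies (both mice switching within the same frame) count
#' as follow events; at 4 fps they indicate coarse temporal sampling and are
#' reported in the `n_direct` attribute. In the default `"strict"` mode an
#' excursion through both incongruent states (e.g. 0,1,2,3) counts as
#' nothing; `"lenient"` mode accepts any congruent-to-other-congruent
#' excursion through incongruent states, for sensitivity analysis.
#'
#' @param seq A `dyad_states` object, or a collapsed state vector.
#' @param mode `"strict"` (two-step or direct only) or `"lenient"`.
#' @return Named integer vector `c(follow_to_freeze, follow_to_move,
#'   follow_total)` with attribute `n_direct`.
#' @export
count_follow <- function(seq, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  cc <- collapsed_of(seq)
  f2f <- 0L; f2m <- 0L; direct <- 0L
  n <- length(cc)
  i <- 1L
  while (i <= n - 1L) {
    s <- cc[i]
    if (s == 0L || s == 3L) {
      other <- 3L - s
      if (cc[i + 1L] == other) {
        direct <- direct + 1L
        if (other == 0L) f2f <- f2f + 1L else f2m <- f2m + 1L
      } else if (mode == "strict") {
        if (i + 2L <= n && cc[i + 1L] %in% c(1L, 2L) && cc[i + 2L] == other) {
          if (other == 0L) f2f <- f2f + 1L else f2m <- f2m + 1L
        }
      } else {
        # lenient: any incongruent excursion that exits into the other state
        j <- i + 1L
        while (j <= n && cc[j] %in% c(1L, 2L)) j <- j + 1L
        if (j <= n && cc[j] == other) {
          if (other == 0L) f2f <- f2f + 1L else f2m <- f2m + 1L
        }
      }
    }
    i <- i + 1L
  }
  out <- c(follow_to_freeze = f2f, follow_to_move = f2m, follow_total = f2f + f2m)
  attr(out, "n_direct") <- direct
  out
}

#' Count "retroact" behaviors
#'
#' A retroact event is a two-step loop that leaves a congruent state through
#' a single incongruent state and returns to the same congruent state: the
#' mouse that broke joint freezing (state 0) or joint moving (state 3)
#' reverses itself before the partner follows. Loops 0 -> 1/2 -> 0 are
#' retroact-to-freeze, loops 3 -> 1/2 -> 3 retroact-to-move. Overlapping
#' triples are each counted.
#'
#' @inheritParams count_follow
#' @param mode `"strict"` (single incongruent state) or `"lenient"` (any
#'   incongruent excursion returning to the same congruent state).
#' @return Named integer vector `c(retroact_to_freeze, retroact_to_move)`.
#' @export
count_retroact <- function(seq, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  cc <- collapsed_of(seq)
  r2f <- 0L; r2m <- 0L
  n <- length(cc)
  for (i in seq_len(max(0L, n - 2L))) {
    s <- cc[i]
    if (s != 0L && s != 3L) next
    if (mode == "strict") {
      hit <- cc[i + 1L] %in% c(1L, 2L) && cc[i + 2L] == s
    } else {
      j <- i + 1L
      while (j <= n && cc[j] %in% c(1L, 2L)) j <- j + 1L
      hit <- j > i + 1L && j <= n && cc[j] == s
    }
    if (hit) {
      if (s == 0L) r2f <- r2f + 1L else r2m <- r2m + 1L
    }
  }
  c(retroact_to_freeze = r2f, retroact_to_move = r2m)
}

#' Follow and retroact counts of one dyad
#'
#' Convenience wrapper assembling [count_follow()] and [count_retroact()]
#' into one record.
#'
#' @inheritParams count_follow
#' @param dyad_id Optional dyad identifier carried into the output.
#' @return One-row data frame: `dyad_id`, `f2f`, `f2m`, `follow_total`,
#'   `r2f`, `r2m`, `n_direct`.
#' @export
behavior_counts <- function(seq, dyad_id = NA_character_,
                            mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  f <- count_follow(seq, mode)
  r <- count_retroact(seq, mode)
  data.frame(
    dyad_id = dyad_id,
    f2f = unname(f["follow_to_freeze"]),
    f2m = unname(f["follow_to_move"]),
    follow_total = unname(f["follow_total"]),
    r2f = unname(r["retroact_to_freeze"]),
    r2m = unname(r["retroact_to_move"]),
    n_direct = attr(f, "n_direct")
  )
}
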