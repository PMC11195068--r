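#' Freezing-bout ethogram for one subject
#'
#' An ethogram holds the manually annotated freezing bouts of a single animal
#' over one session. Bouts are stored as 0-based, half-open frame intervals
#' `[start, end)`. Valid bouts last at least one second (`fps` frames), do not
#' overlap, and are separated by at least one non-freezing frame — adjacent
#' bouts would by definition be a single bout and are treated as an
#' annotation error.
#'
#' @param subject_id Subject identifier (non-empty string).
#' @param bouts A data frame with integer columns `start` and `end`
#'   (half-open, 0-based), or NULL for a subject that never froze.
#' @param layout A [session_layout()].
#' @return An object of class `ethogram`.
#' @examples
#' eth <- ethogram("m1", data.frame(start = c(240L, 300L), end = c(260L, 320L)))
#' freezing_level(bouts_to_trace(eth))
#' @export
ethogram <- function(subject_id, bouts = NULL, layout = session_layout()) {
  if (!is.character(subject_id) || length(subject_id) != 1L || !nzchar(subject_id)) {
    stop("`subject_id` must be a non-empty string")
  }
  if (is.null(bouts) || nrow(bouts) == 0L) {
    bouts <- data.frame(start = integer(0), end = integer(0))
  }
  stopifnot(all(c("start", "end") %in% names(bouts)))
  bouts <- data.frame(start = as.integer(bouts$start), end = as.integer(bouts$end))
  bouts <- bouts[order(bouts$start), , drop = FALSE]
  rownames(bouts) <- NULL
  obj <- structure(
    list(subject_id = subject_id, layout = layout, bouts = bouts),
    class = "ethogram"
  )
  validate_ethogram(obj)
  obj
}

#' Validate ethogram invariants
#'
#' Checks bout ordering, the minimum one-second bout length, non-overlap,
#' the one-frame minimum gap between bouts, and session bounds. Called by
#' [ethogram()]; exposed for use on externally constructed objects.
#'
#' @param x An `ethogram`.
#' @return `x`, invisibly. Throws an error listing every offending bout.
#' @export
validate_ethogram <- function(x) {
  stopifnot(inherits(x, "ethogram"))
  b <- x$bouts
  if (nrow(b) == 0L) return(invisible(x))
  min_len <- x$layout$fps  # >= 1 s of frames
  problems <- character(0)
  bad_len <- which(b$end - b$start < min_len)
  if (length(bad_len)) {
    problems <- c(problems, sprintf(
      "bout [%d, %d) shorter than %d frames (1 s)",
      b$start[bad_len], b$end[bad_len], min_len
    ))
  }
  if (any(b$start < 0L)) {
    problems <- c(problems, sprintf("bout [%d, %d) starts before frame 0",
                                    b$start[b$start < 0L], b$end[b$start < 0L]))
  }
  if (any(b$end > x$layout$n_frames)) {
    over <- b$end > x$layout$n_frames
    problems <- c(problems, sprintf("bout [%d, %d) extends past session end (%d frames)",
                                    b$start[over], b$end[over], x$layout$n_frames))
  }
  if (nrow(b) > 1L) {
    gap <- b$start[-1L] - b$end[-nrow(b)]
    bad_gap <- which(gap < 1L)
    if (length(bad_gap)) {
      problems <- c(problems, sprintf(
        "bouts [%d, %d) and [%d, %d) overlap or touch (adjacent bouts are one bout)",
        b$start[bad_gap], b$end[bad_gap], b$start[bad_gap + 1L], b$end[bad_gap + 1L]
      ))
    }
  }
  if (length(problems)) {
    stop(sprintf("invalid ethogram for subject '%s':\n  %s",
                 x$subject_id, paste(problems, collapse = "\n  ")), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.ethogram <- function(x, ...) {
  cat(sprintf("<ethogram> subject %s: %d freezing bouts, %d frozen frames\n",
              x$subject_id, nrow(x$bouts), sum(x$bouts$end - x$bouts$start)))
  invisible(x)
}

#' Read a freezing-bout annotation table
#'
#' Parses a bout table with columns `subject_id,start_frame,end_frame` into
#' one [ethogram()] per subject. Annotators typically record the first and
#' last frame of each bout inclusively; the default `end_convention =
#' "inclusive"` converts `end_frame` to the package's half-open convention
#' (`end = last + 1`). Use `"exclusive"` for tables already half-open (e.g.
#' ones written by [write_bout_table()] with that convention).
#'
#' @param source Path to a CSV file, a connection, or a data frame.
#' @param layout A [session_layout()] shared by all subjects.
#' @param end_convention `"inclusive"` (default; `end_frame` is the last
#'   frozen frame) or `"exclusive"` (`end_frame` is one past it).
#' @return A named list of `ethogram` objects, one per subject, in order of
#'   first appearance.
#' @seealso [write_bout_table()], [bouts_to_trace()]
#' @export
read_bout_table <- function(source, layout = session_layout(),
                            end_convention = c("inclusive", "exclusive")) {
  end_convention <- match.arg(end_convention)
  tab <- if (is.data.frame(source)) source else {
    utils::read.csv(source, colClasses = c("character", "integer", "integer"))
  }
  required <- c("subject_id", "start_frame", "end_frame")
  if (!all(required %in% names(tab))) {
    stop("bout table must have columns: ", paste(required, collapse = ", "))
  }
  start <- suppressWarnings(as.integer(tab$start_frame))
  end <- suppressWarnings(as.integer(tab$end_frame))
  bad <- which(is.na(start) | is.na(end) | start < 0L | end < 0L)
  if (length(bad)) {
    stop("malformed bout rows (non-negative integer frames required): row ",
         paste(bad, collapse = ", "))
  }
  if (end_convention == "inclusive") end <- end + 1L
  subjects <- unique(as.character(tab$subject_id))
  out <- lapply(subjects, function(sid) {
    sel <- tab$subject_id == sid
    ethogram(sid, data.frame(start = start[sel], end = end[sel]), layout)
  })
  names(out) <- subjects
  out
}

#' Write ethograms back to a bout table
#'
#' Inverse of [read_bout_table()]: `read_bout_table(write_bout_table(x, f))`
#' reproduces `x` exactly when the same `end_convention` is used.
#'
#' @param ethograms A list of `ethogram` objects (or a single one).
#' @param sink File path or connection; NULL to return the table without
#'   writing.
#' @inheritParams read_bout_table
#' @return The bout-table data frame, invisibly.
#' @export
write_bout_table <- function(ethograms, sink = NULL,
                             end_convention = c("inclusive", "exclusive")) {
  end_convention <- match.arg(end_convention)
  if (inherits(ethograms, "ethogram")) ethograms <- list(ethograms)
  rows <- lapply(ethograms, function(e) {
    stopifnot(inherits(e, "ethogram"))
    if (nrow(e$bouts) == 0L) return(NULL)
    data.frame(
      subject_id = e$subject_id,
      start_frame = e$bouts$start,
      end_frame = if (end_convention == "inclusive") e$bouts$end - 1L else e$bouts$end
    )
  })
  tab <- do.call(rbind, c(rows, list(data.frame(subject_id = character(0),
                                                start_frame = integer(0),
                                                end_frame = integer(0)))))
  if (!is.null(sink)) utils::write.csv(tab, sink, row.names = FALSE, quote = FALSE)
  invisible(tab)
}

#' Convert bouts to a per-frame binary freezing trace
#'
#' @param eth An `ethogram`.
#' @param window Half-open 0-based frame interval `c(start, end)`; defaults to
#'   the CS segment of the ethogram's layout.
#' @return An integer vector of 0/1 (1 = freezing) of length
#'   `window[2] - window[1]`, with attributes `window_start` and `fps`.
#' @examples
#' eth <- ethogram("m1", data.frame(start = 240L, end = 248L))
#' sum(bouts_to_trace(eth))  # 8 frozen frames in the CS window
#' @export
bouts_to_trace <- function(eth, window = NULL) {
  stopifnot(inherits(eth, "ethogram"))
  if (is.null(window)) window <- cs_window(eth$layout)
  window <- as.integer(window)
  if (length(window) != 2L || window[1] < 0L || window[2] > eth$layout$n_frames ||
      window[1] >= window[2]) {
    stop("`window` must be a half-open frame interval within the session range")
  }
  n <- window[2] - window[1]
  trace <- integer(n)
  b <- eth$bouts
  if (nrow(b)) {
    lo <- pmax(b$start, window[1])
    hi <- pmin(b$end, window[2])
    keep <- which(lo < hi)
    for (i in keep) trace[(lo[i] - window[1] + 1L):(hi[i] - window[1])] <- 1L
  }
  attr(trace, "window_start") <- window[1]
  attr(trace, "fps") <- eth$layout$fps
  trace
}

#' Recover freezing bouts from a binary trace
#'
#' Utility inverse of [bouts_to_trace()] used by the simulator: runs of 1s in
#' `trace` become bouts, offset by `window_start`.
#'
#' @param trace Integer 0/1 vector.
#' @param window_start 0-based frame index of the first trace sample.
#' @return A data frame with columns `start`, `end` (half-open).
#' @export
trace_to_bouts <- function(trace, window_start = 0L) {
  stopifnot(all(trace %in% c(0L, 1L)))
  r <- rle(as.integer(trace))
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths
  keep <- r$values == 1L
  data.frame(
    start = as.integer(starts[keep] + window_start),
    end = as.integer(stops[keep] + window_start)
  )
}
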