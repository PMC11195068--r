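#' Session layout for a cued fear test
#'
#' Describes the temporal structure of one recording session: a baseline
#' (pre-CS) segment followed by the conditioned-stimulus (CS) segment, sampled
#' at a fixed video frame rate. Frame indices throughout the package are
#' 0-based and intervals are half-open `[start, end)`.
#'
#' @param fps Video frame rate in frames per second (integer, >= 1).
#' @param pre_cs_s Duration of the pre-CS baseline segment in seconds.
#' @param cs_s Duration of the CS segment in seconds.
#'
#' @return An object of class `session_layout`: a list with elements `fps`,
#'   `pre_cs_s`, `cs_s`, `n_frames` (total session frames), `cs_start` and
#'   `cs_end` (0-based frame bounds of the CS segment, half-open).
#'
#' @details The defaults (4 fps, 60 s pre-CS, 120 s CS) give a 720-frame
#'   session whose CS segment spans frames `[240, 720)`, i.e. 480 CS samples.
#'
#' @examples
#' layout <- session_layout()
#' cs_window(layout)       # c(240, 720)
#' @export
session_layout <- function(fps = 4L, pre_cs_s = 60, cs_s = 120) {
  fps <- as.integer(fps)
  if (is.na(fps) || fps < 1L) stop("`fps` must be an integer >= 1")
  if (pre_cs_s <= 0 || cs_s <= 0) stop("segment durations must be positive")
  pre_frames <- as.integer(round(fps * pre_cs_s))
  cs_frames <- as.integer(round(fps * cs_s))
  structure(
    list(
      fps = fps,
      pre_cs_s = pre_cs_s,
      cs_s = cs_s,
      n_frames = pre_frames + cs_frames,
      cs_start = pre_frames,
      cs_end = pre_frames + cs_frames
    ),
    class = "session_layout"
  )
}

#' @rdname session_layout
#' @param layout A `session_layout`.
#' @return `cs_window()` and `pre_cs_window()` return a length-2 integer
#'   vector `c(start, end)`, a half-open 0-based frame interval.
#' @export
cs_window <- function(layout) {
  stopifnot(inherits(layout, "session_layout"))
  c(layout$cs_start, layout$cs_end)
}

#' @rdname session_layout
#' @export
pre_cs_window <- function(layout) {
  stopifnot(inherits(layout, "session_layout"))
  c(0L, layout$cs_start)
}

#' @export
print.session_layout <- function(x, ...) {
  cat(sprintf(
    "<session_layout> %d fps | pre-CS %gs + CS %gs = %d frames (CS frames [%d, %d))\n",
    x$fps, x$pre_cs_s, x$cs_s, x$n_frames, x$cs_start, x$cs_end
  ))
  invisible(x)
}
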