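# Analysis-window selection and key-frame sampling.
#
# Micro-expressions are recognized on the onset-to-apex stretch only: motion
# ramps up to the apex and the relaxation tail adds little. The window starts
# at the onset; the end is the apex unless the apex sits fewer than 10 frames
# after the onset, in which case the window is padded to 10 frames (both ends
# clamped to the offset). N_key frames are then sampled at a ceiling-divided
# interval, always terminating in the window end.

#' Select the analysis window of a clip
#'
#' `start` is the onset. If the resolved apex is fewer than 10 frames past the
#' onset, `end = min(onset + 10, offset)`; otherwise `end = min(apex, offset)`.
#'
#' @param annotation A [clip_annotation()]; an absent apex is resolved with
#'   [resolve_apex()].
#' @return Integer vector `c(start, end)`.
#' @export
select_window <- function(annotation) {
  onset <- annotation$onset
  apex <- resolve_apex(annotation)
  offset <- annotation$offset
  end <- if (apex - onset < 10L) min(onset + 10L, offset) else min(apex, offset)
  c(start = onset, end = as.integer(end))
}

#' Select key frames within a window
#'
#' With `gap = ceiling((end - start) / (n_key + 1))`, the key frames are
#' `min(start + k * gap, end)` for `k = 1 .. n_key - 1` followed by `end`
#' itself. On short windows the clamping produces duplicates; these are kept so
#' the residual sum always pools exactly `n_key` terms and its magnitude scale
#' is independent of clip length.
#'
#' @param start,end Frame indices, `start <= end`.
#' @param n_key Number of key frames (default 5).
#' @return An object of class `keyframe_set`: list with `start`, `end`, `gap`,
#'   `n_key` and `frames` (non-decreasing integer vector of length `n_key`,
#'   ending in `end`).
#' @export
select_keyframes <- function(start, end, n_key = 5) {
  start <- as.integer(start); end <- as.integer(end); n_key <- as.integer(n_key)
  if (start > end) stop("start (", start, ") > end (", end, ")")
  if (n_key < 1L) stop("n_key must be a positive integer")
  gap <- as.integer(ceiling((end - start) / (n_key + 1)))
  frames <- c(pmin(start + seq_len(n_key - 1L) * gap, end), end)
  structure(list(start = start, end = end, gap = gap, n_key = n_key,
                 frames = as.integer(frames)),
            class = "keyframe_set")
}

#' @export
print.keyframe_set <- function(x, ...) {
  cat(sprintf("<keyframe_set [%d, %d] gap=%d: %s>\n", x$start, x$end, x$gap,
              paste(x$frames, collapse = " ")))
  invisible(x)
}
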