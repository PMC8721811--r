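# Pixel residual-sum preprocessing.
#
# A key-frame set is collapsed into one 3-channel image by summing, per pixel
# and channel, the absolute differences between each key frame and the window's
# start frame. ARS folds the sum into 8 bits with a modulus; RRS min-max
# rescales it to [gmin, gmax]. Both turn a short clip into a single image whose
# bright regions are the moving ones, cancelling static appearance.

# Frame at 0-based index i of a clip.
clip_frame <- function(clip, i) {
  if (i < 0L || i >= length(clip$frames))
    stop("clip ", clip$annotation$clip_id, ": frame index ", i, " out of range")
  clip$frames[[i + 1L]]
}

#' Residual-sum map of a clip
#'
#' `diff(x, y, z) = sum over key frames f of |Q_f(x, y, z) - Q_start(x, y, z)|`,
#' where the reference `Q_start` is the frame at the key-frame set's window
#' start. The sum is over exactly `n_key` terms (duplicates included) in plain
#' double/integer arithmetic, so values above 255 are preserved.
#'
#' @param clip A `clip`.
#' @param kf A `keyframe_set` from [select_keyframes()].
#' @return H x W x 3 numeric array of non-negative integers.
#' @export
residual_sum_map <- function(clip, kf) {
  ref <- clip_frame(clip, kf$start)
  acc <- array(0, dim(ref))
  for (f in kf$frames) acc <- acc + abs(clip_frame(clip, f) - ref)
  acc
}

new_residual_image <- function(pixels, method, gmin = 0L, gmax = 255L) {
  structure(list(pixels = pixels, method = method,
                 gmin = as.integer(gmin), gmax = as.integer(gmax)),
            class = "residual_image")
}

#' @export
print.residual_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<residual_image %s %dx%dx%d range [%d, %d]>\n", x$method,
              d[1], d[2], d[3], x$gmin, x$gmax))
  invisible(x)
}

#' Absolute Residual Sum image
#'
#' The residual-sum map reduced modulo 256 (the modulus is applied once to the
#' final sum, not per term). Large accumulated motion therefore wraps around,
#' which trades off small- and large-displacement regions.
#'
#' @inheritParams residual_sum_map
#' @return A `residual_image` with `method = "ARS"` and pixels in 0..255.
#' @export
ars_image <- function(clip, kf) {
  new_residual_image(residual_sum_map(clip, kf) %% 256, "ARS")
}

#' Relative Residual Sum image
#'
#' The residual-sum map min-max rescaled to `[gmin, gmax]`:
#' `rres = (diff - min(diff)) / (max(diff) - min(diff)) * (gmax - gmin) + gmin`,
#' with the minimum and maximum taken globally over all pixels and channels
#' (set `per_channel = TRUE` for a per-channel ablation variant). Values are
#' rounded half-to-even to integers. A constant map (static clip) degenerates
#' to all-`gmin`.
#'
#' @inheritParams residual_sum_map
#' @param gmin,gmax Output range, `gmin < gmax`; defaults 0 and 255.
#' @param per_channel Rescale each channel by its own min/max instead of the
#'   global one.
#' @return A `residual_image` with `method = "RRS"` and pixels in
#'   `[gmin, gmax]`.
#' @export
rrs_image <- function(clip, kf, gmin = 0, gmax = 255, per_channel = FALSE) {
  if (gmin >= gmax) stop("gmin (", gmin, ") must be < gmax (", gmax, ")")
  d <- residual_sum_map(clip, kf)
  rescale <- function(v) {
    lo <- min(v); hi <- max(v)
    if (hi == lo) return(array(gmin, dim(v)))
    round((v - lo) / (hi - lo) * (gmax - gmin) + gmin)
  }
  out <- if (per_channel) {
    res <- d
    for (z in seq_len(dim(d)[3])) res[, , z] <- rescale(d[, , z, drop = FALSE])
    res
  } else rescale(d)
  new_residual_image(out, "RRS", gmin, gmax)
}

#' Raw apex-frame image
#'
#' Baseline preprocessing for ablation: the clip's (resolved) apex frame taken
#' as-is, with no temporal pooling. Useful as the control against which the
#' residual-sum methods are compared.
#'
#' @param clip A `clip`.
#' @return A `residual_image` with `method = "APEX"`.
#' @export
apex_image <- function(clip) {
  new_residual_image(clip_frame(clip, resolve_apex(clip$annotation)), "APEX")
}
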