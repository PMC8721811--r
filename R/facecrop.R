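# Landmark-driven face cropping.
#
# The face box is the tight bounding box of the 68 landmark points, expanded by
# a margin and clamped to the frame. One box — computed from the onset frame's
# landmarks — is applied to every frame of a clip, so residual sums reflect
# facial motion and never crop-box jitter.

#' Build a crop specification from landmarks
#'
#' The box is the tight bounding box of all 68 points, expanded on each side by
#' `margin * max(box width, box height)` and clamped to the frame. Coordinates
#' are half-open pixel intervals, 0-based.
#'
#' @param landmarks 68 x 2 matrix of (x, y) pixel coordinates.
#' @param margin Expansion fraction per side (default 0.1).
#' @param frame_shape `c(H, W)` of the frames the box will be applied to.
#' @param output_size `c(width, height)` the crop will be resampled to
#'   (default 320 x 320, the tiling module's input resolution).
#' @return An object of class `crop_spec` with fields `box`
#'   (`c(left, top, right, bottom)`), `margin`, `output_size`.
#' @export
landmarks_to_box <- function(landmarks, margin = 0.1, frame_shape,
                             output_size = c(320, 320)) {
  lm <- as_landmarks(landmarks)
  if (margin < 0) stop("margin must be >= 0")
  H <- frame_shape[1]; W <- frame_shape[2]
  left <- min(lm[, "x"]); right <- max(lm[, "x"])
  top <- min(lm[, "y"]); bottom <- max(lm[, "y"])
  pad <- margin * max(right - left, bottom - top)
  box <- c(left = max(left - pad, 0), top = max(top - pad, 0),
           right = min(right + pad, W), bottom = min(bottom + pad, H))
  if (box["right"] <= box["left"] || box["bottom"] <= box["top"])
    stop("degenerate crop box from landmarks")
  structure(list(box = box, margin = margin,
                 output_size = as.integer(output_size)),
            class = "crop_spec")
}

#' Crop a frame to a box and resample to a fixed size
#'
#' Bilinear resampling with replicate borders. Output pixel centers are mapped
#' affinely onto the box so that cropping a full frame to its own size is the
#' identity, bit-exactly.
#'
#' @param frame H x W x 3 array (0..255).
#' @param spec A `crop_spec` from [landmarks_to_box()].
#' @return Array of `output_size[2] x output_size[1] x 3`.
#' @export
crop_and_resize <- function(frame, spec) {
  b <- spec$box
  bw <- b[["right"]] - b[["left"]]; bh <- b[["bottom"]] - b[["top"]]
  if (bw <= 0 || bh <= 0) stop("empty crop box")
  ow <- spec$output_size[1]; oh <- spec$output_size[2]
  # sample coordinates of output pixel centers, 0-based continuous
  xs <- b[["left"]] + (seq_len(ow) - 0.5) * (bw / ow) - 0.5
  ys <- b[["top"]] + (seq_len(oh) - 0.5) * (bh / oh) - 0.5
  bilinear_sample(frame, xs, ys)
}

# Sample img at the grid ys x xs (0-based continuous coords, row = y),
# bilinear with border replication. Returns length(ys) x length(xs) x 3.
bilinear_sample <- function(img, xs, ys) {
  H <- dim(img)[1]; W <- dim(img)[2]; C <- dim(img)[3]
  cl <- function(v, n) pmin(pmax(v, 0), n - 1L)
  x0 <- cl(floor(xs), W); y0 <- cl(floor(ys), H)
  x1 <- cl(x0 + 1, W); y1 <- cl(y0 + 1, H)
  fx <- cl(xs, W) - x0; fy <- cl(ys, H) - y0
  oh <- length(ys); ow <- length(xs)
  # expand to the full grid (rows vary with y, columns with x)
  Y0 <- matrix(y0 + 1L, oh, ow); Y1 <- matrix(y1 + 1L, oh, ow)
  X0 <- matrix(x0 + 1L, oh, ow, byrow = TRUE); X1 <- matrix(x1 + 1L, oh, ow, byrow = TRUE)
  FY <- matrix(fy, oh, ow); FX <- matrix(fx, oh, ow, byrow = TRUE)
  out <- array(0, c(oh, ow, C))
  for (z in seq_len(C)) {
    ch <- img[, , z]
    g <- function(Yi, Xi) matrix(ch[cbind(as.vector(Yi), as.vector(Xi))], oh, ow)
    out[, , z] <- (1 - FY) * ((1 - FX) * g(Y0, X0) + FX * g(Y0, X1)) +
      FY * ((1 - FX) * g(Y1, X0) + FX * g(Y1, X1))
  }
  out
}

#' Crop every frame of a clip with one shared box
#'
#' @param clip A `clip`.
#' @param spec A `crop_spec`, typically from the onset frame's landmarks.
#' @param indices Optional 0-based frame indices to crop (default: all frames).
#' @return A `clip` whose frames are the cropped, resampled images. When
#'   `indices` is given, frame `i` of the result corresponds to requested
#'   index `indices[i]` and the annotation is remapped accordingly only if all
#'   of onset/apex/offset are present in `indices`.
#' @export
crop_clip <- function(clip, spec, indices = NULL) {
  if (is.null(indices)) {
    frames <- lapply(clip$frames, crop_and_resize, spec = spec)
    return(new_clip(clip$annotation, frames))
  }
  frames <- lapply(indices, function(i) crop_and_resize(clip_frame(clip, i), spec))
  new_clip(clip$annotation, frames)
}
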