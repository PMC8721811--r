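# Stochastic training-time augmentation.
#
# Four stages applied in a fixed order to the residual image before tiling
# (pre-tiling keeps all 10 tiles of one sample mutually consistent):
#   1. color jitter — brightness, contrast and saturation each scaled by an
#      independent uniform draw from jitter_range, hue shifted by a uniform
#      draw from hue_range (on a [0, 1] hue wheel);
#   2. grayscale conversion with probability grayscale_prob;
#   3. horizontal flip with probability hflip_prob;
#   4. rotation by a uniform draw from rotation_degrees about the center,
#      bilinear with replicate borders.
# All draws come from R's RNG, in a fixed order, so a seeded call is fully
# reproducible.

#' Augmentation configuration
#'
#' Defaults follow the conventional training recipe for micro-expression
#' residual images: photometric jitter in \[20%, 180%\], hue shift in
#' \[-0.5, 0.5\], 20% grayscale, 50% horizontal flip, rotation in
#' \[-15, 15\] degrees.
#'
#' @param jitter_range Multiplicative range for brightness/contrast/saturation.
#' @param hue_range Additive hue-shift range on a `[0, 1]` hue wheel.
#' @param grayscale_prob,hflip_prob Stage probabilities in `[0, 1]`.
#' @param rotation_degrees Rotation range in degrees (clockwise positive).
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(jitter_range = c(0.2, 1.8),
                           hue_range = c(-0.5, 0.5),
                           grayscale_prob = 0.2,
                           hflip_prob = 0.5,
                           rotation_degrees = c(-15, 15)) {
  stopifnot(length(jitter_range) == 2, jitter_range[1] <= jitter_range[2],
            length(hue_range) == 2, hue_range[1] <= hue_range[2],
            grayscale_prob >= 0, grayscale_prob <= 1,
            hflip_prob >= 0, hflip_prob <= 1,
            length(rotation_degrees) == 2,
            rotation_degrees[1] <= rotation_degrees[2])
  structure(list(jitter_range = jitter_range, hue_range = hue_range,
                 grayscale_prob = grayscale_prob, hflip_prob = hflip_prob,
                 rotation_degrees = rotation_degrees),
            class = "augment_config")
}

#' Identity augmentation configuration
#'
#' All ranges collapsed and probabilities zeroed, so [augment_image()] is the
#' identity. Used when training without augmentation.
#' @return An `augment_config`.
#' @export
augment_identity <- function() {
  augment_config(jitter_range = c(1, 1), hue_range = c(0, 0),
                 grayscale_prob = 0, hflip_prob = 0,
                 rotation_degrees = c(0, 0))
}

to_gray <- function(img) {
  g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  array(rep(g, 3L), dim(img))
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

# Vectorized RGB (0..255 arrays) <-> HSV (all components in [0, 1]).
rgb_to_hsv_arr <- function(img) {
  d <- dim(img)
  ch <- function(z) matrix(img[, , z], d[1], d[2])
  r <- ch(1) / 255; g <- ch(2) / 255; b <- ch(3) / 255
  mx <- pmax(r, g, b); mn <- pmin(r, g, b); d <- mx - mn
  h <- matrix(0, nrow(r), ncol(r))
  nz <- d > 0
  rmax <- nz & mx == r; gmax <- nz & !rmax & mx == g; bmax <- nz & !rmax & !gmax
  h[rmax] <- ((g - b)[rmax] / d[rmax]) %% 6
  h[gmax] <- (b - r)[gmax] / d[gmax] + 2
  h[bmax] <- (r - g)[bmax] / d[bmax] + 4
  h <- h / 6
  s <- ifelse(mx > 0, d / mx, 0)
  list(h = h, s = s, v = mx)
}

hsv_to_rgb_arr <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6); f <- h6 - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- v; g <- v; b <- v
  m0 <- i == 0; m1 <- i == 1; m2 <- i == 2; m3 <- i == 3; m4 <- i == 4; m5 <- i >= 5
  r[m1] <- q[m1]; r[m2] <- p[m2]; r[m3] <- p[m3]; r[m4] <- t[m4]
  g[m0] <- t[m0]; g[m3] <- q[m3]; g[m4] <- p[m4]; g[m5] <- p[m5]
  b[m0] <- p[m0]; b[m1] <- p[m1]; b[m2] <- t[m2]; b[m5] <- q[m5]
  out <- array(0, c(dim(h), 3L))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out * 255
}

adjust_brightness <- function(img, f) clamp255(img * f)

adjust_contrast <- function(img, f) {
  m <- mean(to_gray(img)[, , 1])
  clamp255((img - m) * f + m)
}

adjust_saturation <- function(img, f) {
  g <- to_gray(img)
  clamp255(g + (img - g) * f)
}

adjust_hue <- function(img, shift) {
  if (shift == 0) return(img)
  hsv <- rgb_to_hsv_arr(clamp255(img))
  hsv_to_rgb_arr(hsv$h + shift, hsv$s, hsv$v)
}

hflip <- function(img) img[, rev(seq_len(dim(img)[2])), , drop = FALSE]

# Rotate clockwise by `degrees` about the image center, bilinear sampling with
# border replication (exact identity at 0 degrees).
rotate_image <- function(img, degrees) {
  if (degrees == 0) return(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  th <- degrees * pi / 180
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  gx <- matrix(seq_len(W) - 1 - cx, H, W, byrow = TRUE)
  gy <- matrix(seq_len(H) - 1 - cy, H, W)
  # inverse mapping: source coords that land on each output pixel
  sx <- cos(th) * gx - sin(th) * gy + cx
  sy <- sin(th) * gx + cos(th) * gy + cy
  out <- array(0, dim(img))
  x0 <- pmin(pmax(floor(sx), 0), W - 1); y0 <- pmin(pmax(floor(sy), 0), H - 1)
  x1 <- pmin(x0 + 1, W - 1); y1 <- pmin(y0 + 1, H - 1)
  fx <- pmin(pmax(sx, 0), W - 1) - x0; fy <- pmin(pmax(sy, 0), H - 1) - y0
  for (z in seq_len(dim(img)[3])) {
    ch <- img[, , z]
    g <- function(Y, X) matrix(ch[cbind(as.vector(Y + 1), as.vector(X + 1))], H, W)
    out[, , z] <- (1 - fy) * ((1 - fx) * g(y0, x0) + fx * g(y0, x1)) +
      fy * ((1 - fx) * g(y1, x0) + fx * g(y1, x1))
  }
  out
}

#' Apply the four-stage stochastic augmentation
#'
#' Draws, in order: brightness, contrast and saturation factors and a hue
#' shift; a grayscale coin; a flip coin; a rotation angle. Uses the current R
#' RNG state — wrap in `set.seed()` (or `withr::with_seed()`) for
#' reproducibility. Output is clamped to `[0, 255]`; shape is preserved.
#'
#' @param image H x W x 3 array (0..255).
#' @param config An [augment_config()].
#' @return Augmented H x W x 3 array.
#' @export
augment_image <- function(image, config = augment_config()) {
  f_b <- stats::runif(1, config$jitter_range[1], config$jitter_range[2])
  f_c <- stats::runif(1, config$jitter_range[1], config$jitter_range[2])
  f_s <- stats::runif(1, config$jitter_range[1], config$jitter_range[2])
  h_s <- stats::runif(1, config$hue_range[1], config$hue_range[2])
  gray <- stats::runif(1) < config$grayscale_prob
  flip <- stats::runif(1) < config$hflip_prob
  ang <- stats::runif(1, config$rotation_degrees[1], config$rotation_degrees[2])
  img <- image
  if (f_b != 1) img <- adjust_brightness(img, f_b)
  if (f_c != 1) img <- adjust_contrast(img, f_c)
  if (f_s != 1) img <- adjust_saturation(img, f_s)
  img <- adjust_hue(img, h_s)
  if (gray) img <- to_gray(img)
  if (flip) img <- hflip(img)
  img <- rotate_image(img, ang)
  clamp255(img)
}
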