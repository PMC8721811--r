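# Cropped Gaussian Pyramid with Overlapping (CGPO).
#
# A 320x320 input is tiled at two pyramid levels: the 2x-downsampled image
# contributes a single full 160x160 tile (index 0), and the full-resolution
# level is cut into a grid of overlapping 160x160 crops whose stride is
# tile_size * (1 - alpha). At the default alpha = 0.3 the grid offsets are
# {0, 112, 160} in each axis, giving 9 crops and 10 tiles in total. Tile order
# (downsampled first, then row-major with y outer) is fixed: downstream
# position embeddings are ordinal and must be stable across runs.

#' CGPO configuration
#'
#' @param input_size Input resolution (square), default 320.
#' @param tile_size Tile resolution, default 160; must be `input_size / 2` for
#'   the two-level geometry.
#' @param alpha Overlap factor in `[0, 1)`; default 0.3. Adjacent grid tiles
#'   share a fraction `alpha` of their width (up to rounding and edge
#'   clamping).
#' @param levels Number of pyramid levels; only 2 is supported.
#' @return An object of class `cgpo_config`.
#' @export
cgpo_config <- function(input_size = 320, tile_size = 160, alpha = 0.3,
                        levels = 2) {
  if (levels != 2) stop("only the two-level pyramid geometry is supported")
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)")
  if (input_size != 2 * tile_size)
    stop("input_size must be twice tile_size for the two-level geometry")
  structure(list(input_size = as.integer(input_size),
                 tile_size = as.integer(tile_size),
                 alpha = alpha, levels = 2L),
            class = "cgpo_config")
}

# Separable 5-tap binomial (1,4,6,4,1)/16 filter along rows, symmetric
# (edge-repeating) reflection at the borders.
.binomial5 <- c(1, 4, 6, 4, 1) / 16

blur_rows <- function(m) {
  n <- nrow(m)
  # symmetric reflection with edge repeated: ..., 2, 1 | 1, 2, ..., n | n, n-1, ...
  ref <- function(i) {
    i <- ifelse(i < 1L, 1L - i, i)
    ifelse(i > n, 2L * n + 1L - i, i)
  }
  out <- matrix(0, n, ncol(m))
  for (k in -2:2)
    out <- out + .binomial5[k + 3L] * m[ref(seq_len(n) + k), , drop = FALSE]
  out
}

#' Gaussian-pyramid downsampling by 2
#'
#' Blurs with the separable 5x5 binomial kernel (weights 1,4,6,4,1 normalized)
#' using symmetric (edge-repeating) reflection at the borders, then keeps the
#' even-indexed rows and columns (0-based).
#'
#' @param image 2N x 2M x C array with even side lengths.
#' @return N x M x C array.
#' @export
pyramid_downsample <- function(image) {
  d <- dim(image)
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L)
    stop("pyramid_downsample requires even side lengths, got ",
         d[1], "x", d[2])
  out <- array(0, c(d[1] %/% 2L, d[2] %/% 2L, d[3]))
  for (z in seq_len(d[3])) {
    b <- t(blur_rows(t(blur_rows(image[, , z]))))  # rows, then columns
    out[, , z] <- b[seq(1L, d[1], by = 2L), seq(1L, d[2], by = 2L)]
  }
  out
}

#' Grid offsets for overlapping tiles
#'
#' Offsets start at 0 and advance by `stride = round(tile_size * (1 - alpha))`;
#' any offset whose tile would overhang the image is clamped to
#' `image_size - tile_size`, and duplicates are dropped (order preserved). For
#' `image_size = 320, tile_size = 160, alpha = 0.3` this yields `{0, 112, 160}`.
#'
#' @param image_size,tile_size Integer sizes, `tile_size <= image_size`.
#' @param alpha Overlap factor in `[0, 1)`.
#' @return Integer vector of 0-based offsets.
#' @export
grid_positions <- function(image_size, tile_size, alpha) {
  if (tile_size > image_size)
    stop("tile_size (", tile_size, ") exceeds image size (", image_size, ")")
  stride <- as.integer(round(tile_size * (1 - alpha)))
  if (stride < 1L) stride <- 1L
  offs <- seq(0L, image_size - tile_size + stride - 1L, by = stride)
  offs <- pmin(offs, image_size - tile_size)
  unique(as.integer(offs))
}

#' Cut an image into CGPO tiles
#'
#' Tile 0 is the 2x pyramid-downsampled full image; tiles 1..k are the
#' full-resolution overlapping crops at the cartesian product of
#' [grid_positions()] offsets, ordered row-major (y outer, x inner). With the
#' default configuration this yields exactly 10 tiles of 160 x 160.
#'
#' @param image `input_size x input_size x 3` array.
#' @param config A [cgpo_config()].
#' @return An object of class `tile_set`: list with `tiles` (each a list with
#'   `index`, `level`, `x_offset`, `y_offset`, `image`) and `config`.
#' @export
cgpo_tiles <- function(image, config = cgpo_config()) {
  d <- dim(image)
  if (d[1] != config$input_size || d[2] != config$input_size)
    stop("expected ", config$input_size, "x", config$input_size,
         " input, got ", d[1], "x", d[2])
  ts <- config$tile_size
  tiles <- list(list(index = 0L, level = 1L, x_offset = 0L, y_offset = 0L,
                     image = pyramid_downsample(image)))
  offs <- grid_positions(config$input_size, ts, config$alpha)
  i <- 1L
  for (oy in offs) for (ox in offs) {
    tiles[[i + 1L]] <- list(index = i, level = 0L,
                            x_offset = ox, y_offset = oy,
                            image = image[oy + seq_len(ts), ox + seq_len(ts), ,
                                          drop = FALSE])
    i <- i + 1L
  }
  structure(list(tiles = tiles, config = config), class = "tile_set")
}

#' @export
print.tile_set <- function(x, ...) {
  cat(sprintf("<tile_set: %d tiles of %dx%d, alpha=%.2f>\n",
              length(x$tiles), x$config$tile_size, x$config$tile_size,
              x$config$alpha))
  invisible(x)
}

#' @export
length.tile_set <- function(x) length(x$tiles)
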