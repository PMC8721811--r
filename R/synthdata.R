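# Synthetic micro-expression clips.
#
# Real micro-expression datasets are access-restricted, so the package ships a
# generator with the statistical structure the recognizer relies on: short
# clips of a schematic face in which a class-specific facial region brightens
# with an amplitude that ramps from zero at the onset to a peak at the apex
# and relaxes toward the offset, under per-pixel Gaussian noise and per-frame
# multiplicative illumination drift. Subjects differ in facial appearance
# (geometry jitter, intensity jitter, and subject-specific blotches) but share
# the class-region semantics, so leave-one-subject-out generalization is
# meaningful and subject identity is a genuine confound for any method that
# looks at raw frames.

#' Synthetic dataset configuration
#'
#' Defaults emulate a small composite micro-expression corpus: 6 subjects with
#' 6 clips each over 3 classes, 320 x 320 frames, 24-frame clips, a peak
#' intensity perturbation of 40 (out of 255) — micro-expressions are subtle —
#' pixel noise of sd 3 and illumination drift within +/-2%.
#'
#' @param n_subjects,clips_per_subject,n_classes Corpus shape.
#' @param frame_size Square frame side in pixels.
#' @param clip_length Frames per clip.
#' @param motion_amplitude Peak intensity delta at the apex (0..255 scale).
#' @param noise_sigma Per-pixel Gaussian noise sd.
#' @param illumination_drift Multiplicative per-frame range `c(lo, hi)`.
#' @param seed Base seed; every subject/clip derives its own stream from it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 6, clips_per_subject = 6, n_classes = 3,
                         frame_size = 320, clip_length = 24,
                         motion_amplitude = 40, noise_sigma = 3,
                         illumination_drift = c(0.98, 1.02), seed = 1) {
  stopifnot(n_classes >= 2, n_classes <= 3, motion_amplitude >= 0,
            noise_sigma >= 0, clip_length >= 12,
            illumination_drift[1] <= illumination_drift[2])
  structure(list(n_subjects = as.integer(n_subjects),
                 clips_per_subject = as.integer(clips_per_subject),
                 n_classes = as.integer(n_classes),
                 frame_size = as.integer(frame_size),
                 clip_length = as.integer(clip_length),
                 motion_amplitude = motion_amplitude,
                 noise_sigma = noise_sigma,
                 illumination_drift = illumination_drift,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Class labels and the facial regions their motion is localized to, as
# fractions of the frame: class 1 -> mouth corner, class 2 -> brow,
# class 3 -> nose wing.
synth_classes <- function(n_classes = 3) {
  c("negative", "positive", "surprise")[seq_len(n_classes)]
}

#' Class-region centers of the synthetic face
#'
#' @param size Frame side in pixels.
#' @return 3 x 2 matrix of (x, y) centers: mouth corner, brow, nose.
#' @export
synth_class_regions <- function(size) {
  rbind(mouth = c(x = 0.38, y = 0.72),
        brow = c(x = 0.62, y = 0.30),
        nose = c(x = 0.50, y = 0.52)) * size
}

# Additive elliptical patch on channel arrays.
add_ellipse <- function(img, cx, cy, rx, ry, rgb) {
  size_y <- dim(img)[1]; size_x <- dim(img)[2]
  gx <- matrix(seq_len(size_x) - 1, size_y, size_x, byrow = TRUE)
  gy <- matrix(seq_len(size_y) - 1, size_y, size_x)
  mask <- ((gx - cx) / rx)^2 + ((gy - cy) / ry)^2 <= 1
  for (z in 1:3) {
    ch <- img[, , z]
    ch[mask] <- rgb[z]
    img[, , z] <- ch
  }
  img
}

gauss_bump <- function(size, cx, cy, sigma) {
  gx <- matrix(seq_len(size) - 1, size, size, byrow = TRUE)
  gy <- matrix(seq_len(size) - 1, size, size)
  exp(-((gx - cx)^2 + (gy - cy)^2) / (2 * sigma^2))
}

#' Generate a subject's neutral face
#'
#' Deterministic schematic face: background, elliptical skin region, eyes,
#' brows, nose and mouth patches, with per-subject jitter of positions and
#' intensities plus subject-specific low-amplitude blotches (moles/shading)
#' drawn from `subject_seed`. The same seed always yields the same face.
#'
#' @param subject_seed Integer seed identifying the subject.
#' @param size Frame side in pixels.
#' @return List with `image` (size x size x 3 array, 0..255) and `landmarks`
#'   (68 x 2 matrix).
#' @export
generate_subject_face <- function(subject_seed, size = 320) {
  with_seed(subject_seed, {
    s <- size
    img <- array(stats::runif(1, 70, 100), c(s, s, 3))
    jit <- function(a, b) stats::runif(1, a, b)
    # face ellipse
    fcx <- s * jit(0.47, 0.53); fcy <- s * jit(0.49, 0.55)
    frx <- s * jit(0.30, 0.36); fry <- s * jit(0.38, 0.44)
    skin <- c(jit(160, 195), jit(130, 165), jit(105, 140))
    img <- add_ellipse(img, fcx, fcy, frx, fry, skin)
    # eyes, brows, nose, mouth relative to the face ellipse
    eye_dx <- frx * 0.45; eye_y <- fcy - fry * 0.25
    eye_col <- rep(jit(30, 60), 3)
    img <- add_ellipse(img, fcx - eye_dx, eye_y, frx * 0.16, fry * 0.07, eye_col)
    img <- add_ellipse(img, fcx + eye_dx, eye_y, frx * 0.16, fry * 0.07, eye_col)
    brow_y <- eye_y - fry * 0.15
    brow_col <- rep(jit(50, 90), 3)
    img <- add_ellipse(img, fcx - eye_dx, brow_y, frx * 0.20, fry * 0.035, brow_col)
    img <- add_ellipse(img, fcx + eye_dx, brow_y, frx * 0.20, fry * 0.035, brow_col)
    nose_y <- fcy + fry * 0.10
    img <- add_ellipse(img, fcx, nose_y, frx * 0.10, fry * 0.14,
                       skin * jit(0.80, 0.92))
    mouth_y <- fcy + fry * 0.45
    img <- add_ellipse(img, fcx, mouth_y, frx * 0.32, fry * 0.08,
                       c(jit(120, 170), jit(60, 90), jit(60, 90)))
    # subject-specific blotches: appearance clutter shared by all the
    # subject's clips (static, so residual sums cancel it)
    for (b in seq_len(10)) {
      bx <- fcx + stats::runif(1, -0.8, 0.8) * frx
      by <- fcy + stats::runif(1, -0.8, 0.8) * fry
      amp <- stats::runif(1, -25, 25)
      bump <- gauss_bump(s, bx, by, stats::runif(1, 6, 18)) * amp
      for (z in 1:3) img[, , z] <- img[, , z] + bump
    }
    img <- clamp255(img)
    landmarks <- face_landmarks(fcx, fcy, frx, fry, eye_dx, eye_y, brow_y,
                                nose_y, mouth_y, s)
    list(image = img, landmarks = landmarks)
  })
}

# 68-point layout consistent with the schematic geometry: 17 jaw, 2 x 5 brows,
# 9 nose, 2 x 6 eyes, 20 mouth.
face_landmarks <- function(fcx, fcy, frx, fry, eye_dx, eye_y, brow_y, nose_y,
                           mouth_y, size) {
  th <- seq(pi, 2 * pi, length.out = 17)           # jaw along lower ellipse
  jaw <- cbind(fcx + frx * cos(th), fcy - fry * sin(th))
  brow <- function(cx) cbind(cx + frx * 0.20 * seq(-1, 1, length.out = 5), brow_y)
  nose <- cbind(fcx + frx * 0.10 * c(0, 0, 0, 0, seq(-1, 1, length.out = 5)),
                c(seq(nose_y - fry * 0.14, nose_y + fry * 0.10, length.out = 4),
                  rep(nose_y + fry * 0.14, 5)))
  eye <- function(cx) {
    a <- seq(0, 2 * pi, length.out = 7)[-7]
    cbind(cx + frx * 0.16 * cos(a), eye_y + fry * 0.07 * sin(a))
  }
  a <- seq(0, 2 * pi, length.out = 21)[-21]
  mouth <- cbind(fcx + frx * 0.32 * cos(a), mouth_y + fry * 0.08 * sin(a))
  pts <- rbind(jaw, brow(fcx - eye_dx), brow(fcx + eye_dx), nose,
               eye(fcx - eye_dx), eye(fcx + eye_dx), mouth)
  pts[, 1] <- pmin(pmax(pts[, 1], 0), size - 1)
  pts[, 2] <- pmin(pmax(pts[, 2], 0), size - 1)
  as_landmarks(pts)
}

#' Generate one synthetic clip
#'
#' Frame `t` adds a Gaussian-bump intensity perturbation centered in the
#' class's designated facial region (see [synth_class_regions()]), with
#' amplitude 0 before the onset, ramping linearly to `motion_amplitude` at the
#' apex, then relaxing linearly to a quarter of the peak at the offset; i.i.d.
#' Gaussian pixel noise and a per-frame illumination factor are applied on
#' top, and the result is clamped to 8 bits. Deterministic given
#' `(clip_seed, class_id)`.
#'
#' @param base_face Result of [generate_subject_face()].
#' @param class_id Integer in `1..n_classes`.
#' @param config A [synth_config()].
#' @param clip_seed Integer seed for this clip's random stream.
#' @param subject_id,clip_id Identifiers for the annotation.
#' @return A `clip` with its annotation and a `landmarks` attribute.
#' @export
generate_clip <- function(base_face, class_id, config, clip_seed,
                          subject_id = "s01", clip_id = "c01") {
  stopifnot(class_id >= 1, class_id <= config$n_classes)
  with_seed(clip_seed, {
    s <- config$frame_size
    L <- config$clip_length
    onset <- sample(1:3, 1)
    apex <- min(onset + sample(8:13, 1), L - 3L)
    offset <- min(apex + sample(4:8, 1), L - 1L)
    region <- synth_class_regions(s)[class_id, ]
    center <- region + stats::runif(2, -4, 4)
    bump <- array(gauss_bump(s, center[1], center[2], sigma = s * 0.045),
                  c(s, s, 3))
    amp_at <- function(t) {
      if (t <= onset) return(0)
      if (t <= apex)
        return(config$motion_amplitude * (t - onset) / max(apex - onset, 1))
      a <- config$motion_amplitude
      a + (0.25 * a - a) * min((t - apex) / max(offset - apex, 1), 1)
    }
    frames <- vector("list", L)
    for (t in seq_len(L) - 1L) {
      fr <- base_face$image + bump * amp_at(t)
      if (config$noise_sigma > 0)
        fr <- fr + array(stats::rnorm(length(fr), sd = config$noise_sigma),
                         dim(fr))
      dr <- config$illumination_drift
      if (dr[1] != 1 || dr[2] != 1) fr <- fr * stats::runif(1, dr[1], dr[2])
      frames[[t + 1L]] <- round(clamp255(fr))
    }
    ann <- clip_annotation(subject_id, clip_id, onset = onset, apex = apex,
                           offset = offset,
                           label = synth_classes(config$n_classes)[class_id])
    cl <- new_clip(ann, frames)
    attr(cl, "landmarks") <- base_face$landmarks
    cl
  })
}

#' Generate a full synthetic corpus
#'
#' Subjects get deterministic per-subject faces; clips cycle through the
#' classes so every subject holds a near-balanced class mix.
#'
#' @param config A [synth_config()].
#' @param transform Optional function applied to each clip as it is
#'   generated; its result is stored in place of the clip. Passing e.g. a
#'   [preprocess_clip()] wrapper keeps at most one clip's frames in memory at
#'   a time, which matters at full frame size.
#' @return List of `clip` objects (each carrying a `landmarks` attribute), or
#'   of `transform` results.
#' @export
generate_dataset <- function(config = synth_config(), transform = NULL) {
  out <- list()
  k <- 0L
  for (su in seq_len(config$n_subjects)) {
    face <- generate_subject_face(config$seed * 1000L + su, config$frame_size)
    for (ci in seq_len(config$clips_per_subject)) {
      k <- k + 1L
      class_id <- ((ci - 1L) %% config$n_classes) + 1L
      cl <- generate_clip(
        face, class_id, config,
        clip_seed = config$seed * 100000L + su * 1000L + ci,
        subject_id = sprintf("s%02d", su), clip_id = sprintf("c%02d", ci))
      out[[k]] <- if (is.null(transform)) cl else transform(cl)
    }
  }
  out
}

#' Generate and preprocess a synthetic corpus in one streaming pass
#'
#' Equivalent to [generate_dataset()] followed by [preprocess_dataset()] for
#' each requested method, but each clip's frames are discarded as soon as its
#' residual images are computed, so memory stays flat. All methods see the
#' identical clips.
#'
#' @param config A [synth_config()].
#' @param methods Character vector over `{"rrs", "ars", "apex"}`.
#' @param ... Passed to [preprocess_clip()].
#' @return Named list (one entry per method) of sample lists as produced by
#'   [preprocess_dataset()].
#' @export
synth_samples <- function(config = synth_config(), methods = "rrs", ...) {
  per_clip <- generate_dataset(config, transform = function(cl) {
    lapply(stats::setNames(methods, methods), function(m)
      list(image = preprocess_clip(cl, method = m, ...),
           label = cl$annotation$label,
           subject = cl$annotation$subject_id,
           clip_id = cl$annotation$clip_id))
  })
  lapply(stats::setNames(methods, methods), function(m)
    lapply(per_clip, `[[`, m))
}

#' Write a synthetic corpus to disk
#'
#' Produces the on-disk layout the readers expect: one frame directory per
#' clip (`<subject>_<clip>/0000.png`, ...), an `annotations.csv`, and one
#' landmark CSV per clip under `landmarks/`.
#'
#' @param clips Result of [generate_dataset()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_synth_dataset <- function(clips, out_dir) {
  dir.create(file.path(out_dir, "landmarks"), recursive = TRUE,
             showWarnings = FALSE)
  for (cl in clips) {
    stem <- paste0(cl$annotation$subject_id, "_", cl$annotation$clip_id)
    write_clip(cl, file.path(out_dir, stem))
    write_landmarks(attr(cl, "landmarks"),
                    file.path(out_dir, "landmarks", paste0(stem, ".csv")))
  }
  write_annotations(lapply(clips, `[[`, "annotation"),
                    file.path(out_dir, "annotations.csv"))
  invisible(out_dir)
}
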