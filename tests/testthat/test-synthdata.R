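test_that("subject faces are deterministic in the seed and well-formed", {
  f1 <- generate_subject_face(77, size = 96)
  f2 <- generate_subject_face(77, size = 96)
  expect_identical(f1, f2)
  expect_equal(dim(f1$image), c(96, 96, 3))
  expect_true(all(f1$image >= 0 & f1$image <= 255))
  expect_equal(dim(f1$landmarks), c(68, 2))
  expect_true(all(f1$landmarks >= 0 & f1$landmarks <= 95))
  f3 <- generate_subject_face(78, size = 96)
  expect_gt(sum(f1$image != f3$image), 0)
})

test_that("clips are deterministic and carry valid annotations", {
  cfg <- synth_config(frame_size = 96, clip_length = 16)
  face <- generate_subject_face(5, 96)
  c1 <- generate_clip(face, 1, cfg, clip_seed = 9)
  c2 <- generate_clip(face, 1, cfg, clip_seed = 9)
  expect_identical(c1, c2)
  a <- c1$annotation
  expect_true(a$onset < a$apex && a$apex <= a$offset &&
                a$offset < cfg$clip_length)
  expect_length(c1$frames, cfg$clip_length)
  expect_equal(a$label, "negative")
})

test_that("a static clip propagates to zero ARS and all-gmin RRS", {
  cfg <- synth_config(frame_size = 64, clip_length = 12, motion_amplitude = 0,
                      noise_sigma = 0, illumination_drift = c(1, 1))
  face <- generate_subject_face(3, 64)
  cl <- generate_clip(face, 2, cfg, clip_seed = 4)
  expect_true(all(vapply(cl$frames, identical, logical(1), cl$frames[[1]])))
  w <- select_window(cl$annotation)
  kf <- select_keyframes(w["start"], w["end"], 5)
  expect_true(all(ars_image(cl, kf)$pixels == 0))
  expect_true(all(rrs_image(cl, kf, gmin = 7, gmax = 200)$pixels == 7))
})

test_that("noise-free motion concentrates the residual in the class region", {
  cfg <- synth_config(frame_size = 128, clip_length = 16, noise_sigma = 0,
                      illumination_drift = c(1, 1))
  regions <- synth_class_regions(128)
  set.seed(32)
  for (i in 1:50) {
    cls <- ((i - 1) %% 3) + 1
    face <- generate_subject_face(200 + i, 128)
    cl <- generate_clip(face, cls, cfg, clip_seed = 300 + i)
    w <- select_window(cl$annotation)
    kf <- select_keyframes(w["start"], w["end"], 5)
    px <- ars_image(cl, kf)$pixels
    flat <- which(px == max(px), arr.ind = TRUE)[1, ]
    am <- c(x = unname(flat["dim2"]) - 1, y = unname(flat["dim1"]) - 1)
    dists <- sqrt(rowSums((regions - matrix(am, 3, 2, byrow = TRUE))^2))
    expect_equal(unname(which.min(dists)), cls)
  }
})

test_that("residual energy separates the class regions at default amplitudes", {
  cfg <- synth_config(frame_size = 128, clip_length = 16)
  regions <- synth_class_regions(128)
  region_energy <- function(map, center, radius = 128 * 0.07) {
    gx <- matrix(seq_len(128) - 1, 128, 128, byrow = TRUE)
    gy <- matrix(seq_len(128) - 1, 128, 128)
    mask <- (gx - center[1])^2 + (gy - center[2])^2 <= radius^2
    mean(map[, , 1][mask])
  }
  ratios <- c()
  for (i in 1:30) {
    cls <- ((i - 1) %% 3) + 1
    face <- generate_subject_face(400 + i, 128)
    cl <- generate_clip(face, cls, cfg, clip_seed = 500 + i)
    w <- select_window(cl$annotation)
    kf <- select_keyframes(w["start"], w["end"], 5)
    map <- residual_sum_map(cl, kf)
    own <- region_energy(map, regions[cls, ])
    other <- max(sapply(setdiff(1:3, cls), function(k)
      region_energy(map, regions[k, ])))
    ratios <- c(ratios, own / other)
  }
  expect_gt(mean(ratios), 2)     # own-region energy clearly dominates
  expect_true(all(ratios > 1))
})

test_that("a corpus streams to per-method samples with balanced labels", {
  cfg <- synth_config(n_subjects = 2, clips_per_subject = 3, frame_size = 64,
                      clip_length = 12, seed = 3)
  out <- synth_samples(cfg, methods = c("rrs", "apex"), output_size = 32)
  expect_named(out, c("rrs", "apex"))
  expect_length(out$rrs, 6)
  expect_equal(dim(out$rrs[[1]]$image$pixels), c(32, 32, 3))
  expect_equal(out$rrs[[1]]$image$method, "RRS")
  expect_equal(out$apex[[4]]$image$method, "APEX")
  labels <- vapply(out$rrs, `[[`, character(1), "label")
  expect_equal(sort(unique(labels)), c("negative", "positive", "surprise"))
  # same clips underlie both methods
  expect_equal(vapply(out$apex, `[[`, character(1), "clip_id"),
               vapply(out$rrs, `[[`, character(1), "clip_id"))
})

test_that("a corpus written to disk reads back bit-exactly", {
  cfg <- synth_config(n_subjects = 2, clips_per_subject = 2, frame_size = 48,
                      clip_length = 12, seed = 8)
  clips <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_synth_dataset(clips, dir)
  back <- read_dataset(dir)
  expect_length(back, 4)
  expect_identical(back[[1]]$frames, clips[[1]]$frames)
  expect_equal(back[[3]]$annotation, clips[[3]]$annotation)
  expect_equal(attr(back[[2]], "landmarks"), attr(clips[[2]], "landmarks"),
               tolerance = 1e-6)
})
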