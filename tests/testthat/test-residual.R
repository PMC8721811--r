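test_that("residual sums accumulate absolute differences without overflow", {
  # single pixel: |12-10| + |250-10| + |10-10| + |60-10| + |10-10| = 292
  cl <- make_clip(lapply(c(10, 12, 250, 10, 60, 10),
                         function(v) array(v, c(1, 1, 3))))
  kf <- kf_literal(0, 1:5)
  expect_equal(unique(as.vector(residual_sum_map(cl, kf))), 292)
  expect_equal(unique(as.vector(ars_image(cl, kf)$pixels)), 292 %% 256)

  # n_key all-255 frames against an all-0 start: 5 * 255 everywhere
  cl2 <- make_clip(c(list(array(0, c(2, 2, 3))),
                     replicate(5, array(255, c(2, 2, 3)), simplify = FALSE)))
  expect_equal(unique(as.vector(residual_sum_map(cl2, kf_literal(0, 1:5)))), 1275)

  # key frames identical to the start frame: all-zero map
  cl3 <- make_clip(replicate(6, array(77, c(2, 2, 3)), simplify = FALSE))
  expect_true(all(residual_sum_map(cl3, kf_literal(0, 1:5)) == 0))
  expect_true(all(ars_image(cl3, kf_literal(0, 1:5))$pixels == 0))
  expect_true(all(rrs_image(cl3, kf_literal(0, 1:5))$pixels == 0))  # all-gmin
})

test_that("ARS wraps at 256 and RRS hits its endpoints", {
  mk <- function(vals) make_clip(list(array(0, c(1, length(vals), 3)),
                                      array(rep(vals, 3), c(1, length(vals), 3))))
  kf <- kf_literal(0, 1)
  expect_equal(unique(as.vector(ars_image(mk(256), kf)$pixels)), 0)
  expect_equal(as.vector(rrs_image(mk(c(0, 100)), kf)$pixels[1, , 1]), c(0, 255))
  # midpoint 127.5 rounds half-to-even to 128
  expect_equal(as.vector(rrs_image(mk(c(10, 20, 30)), kf)$pixels[1, , 1]),
               c(0, 128, 255))
  expect_error(rrs_image(mk(c(0, 1)), kf, gmin = 10, gmax = 10), "gmax")
})

test_that("ARS and RRS match the per-pixel loop oracles on random clips", {
  set.seed(7)
  for (i in 1:100) {
    cl <- random_clip(6)
    kf <- kf_literal(0, sample(1:5, 5, replace = TRUE))
    expect_identical(ars_image(cl, kf)$pixels, oracle_ars(cl, kf))
    expect_identical(rrs_image(cl, kf)$pixels, oracle_rrs(cl, kf))
    px <- ars_image(cl, kf)$pixels
    expect_true(all(px >= 0 & px <= 255))
    rr <- rrs_image(cl, kf, gmin = 16, gmax = 240)$pixels
    expect_true(all(rr >= 16 & rr <= 240))
    expect_true(any(rr == 16) && any(rr == 240))  # endpoints attained
  }
})

test_that("key-frame order is irrelevant; constant shifts affect ARS not RRS", {
  set.seed(8)
  cl <- random_clip(6)
  kf <- kf_literal(0, c(1, 2, 3, 4, 5))
  kp <- kf_literal(0, c(4, 2, 5, 1, 3))
  expect_identical(ars_image(cl, kf)$pixels, ars_image(cl, kp)$pixels)
  expect_identical(rrs_image(cl, kf)$pixels, rrs_image(cl, kp)$pixels)

  # adding a constant to every diff: build two-frame clips whose diff is v
  # and v + 40; min-max scaling is shift-invariant, the modulus is not
  v <- matrix(c(100, 140, 220, 250), 2)
  mkd <- function(d) make_clip(list(array(0, c(2, 2, 3)),
                                    array(rep(d, 3), c(2, 2, 3))))
  kf1 <- kf_literal(0, 1)
  expect_identical(rrs_image(mkd(v), kf1)$pixels,
                   rrs_image(mkd(v + 40), kf1)$pixels)
  expect_false(identical(ars_image(mkd(v), kf1)$pixels,
                         ars_image(mkd(v + 40), kf1)$pixels))
})

test_that("per-channel RRS rescales each channel independently", {
  fr0 <- array(0, c(1, 2, 3))
  fr1 <- fr0; fr1[1, , 1] <- c(0, 50); fr1[1, , 2] <- c(0, 200); fr1[1, , 3] <- c(10, 10)
  cl <- make_clip(list(fr0, fr1))
  out <- rrs_image(cl, kf_literal(0, 1), per_channel = TRUE)$pixels
  expect_equal(out[1, , 1], c(0, 255))
  expect_equal(out[1, , 2], c(0, 255))
  expect_equal(out[1, , 3], c(0, 0))     # constant channel collapses to gmin
})

test_that("raw apex baseline returns the untouched apex frame", {
  frames <- lapply(1:5, function(i) array(i * 10, c(2, 2, 3)))
  cl <- make_clip(frames, onset = 0, apex = 3, offset = 4)
  expect_identical(apex_image(cl)$pixels, frames[[4]])
})
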