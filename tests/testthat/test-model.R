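test_that("feature extraction yields one 24-d vector per tile, sharing weights", {
  set.seed(20)
  model <- cropnet(c("a", "b", "c"), backbone = tiny_backbone(), seed = 2)
  img <- array(runif(320 * 320 * 3) * 255, c(320, 320, 3))
  Z <- extract_features(cgpo_tiles(img), model)
  expect_equal(dim(Z), c(10, 24))
  # identical tiles map to identical features (one shared extractor)
  tiles <- replicate(10, img[1:160, 1:160, , drop = FALSE], simplify = FALSE)
  Z2 <- extract_features(tiles, model)
  expect_true(all(apply(Z2, 2, function(col) max(abs(col - col[1]))) < 1e-10))
  # deterministic given the same model
  expect_identical(Z, extract_features(cgpo_tiles(img), model))
  expect_error(extract_features(tiles[1:9], model), "expected 10 tiles")
})

test_that("position embeddings have the stated moments and are seeded", {
  p <- init_position_embeddings(dim = 1000, count = 1000, seed = 42)
  expect_lt(abs(mean(p)), 0.002)
  expect_lt(abs(mean(p^2) - mean(p)^2 - 0.2), 0.002)
  expect_identical(p, init_position_embeddings(1000, 1000, seed = 42))
  expect_equal(dim(init_position_embeddings()), c(9, 24))
})

test_that("fusion adds embeddings to cropped tiles only and concatenates", {
  set.seed(21)
  z <- matrix(rnorm(10 * 24), 10, 24)
  p <- matrix(rnorm(9 * 24), 9, 24)
  f <- fuse(z, p)
  expect_length(f, 240)
  # blockwise oracle
  expected <- c(z[1, ], as.vector(t(z[-1, ] + p)))
  expect_equal(f, expected)
  expect_equal(fuse(z, p * 0), as.vector(t(z)))   # zero embeddings pass through
  zb <- matrix(0, 10, 24); pb <- matrix(0, 9, 24); pb[3, 7] <- 1
  fb <- fuse(zb, pb)
  expect_equal(which(fb != 0), (3 + 1 - 1) * 24 + 7)  # block of tile 3, pos 7
  expect_error(fuse(z, p[1:8, ]), "shape")
})

test_that("label smoothing reduces to cross-entropy and to log C", {
  lg <- c(2.0, -1.0, 0.5)
  expect_equal(label_smoothing_loss(lg, 1, 0),
               -(lg[1] - log(sum(exp(lg)))))
  for (C in c(2, 5, 9))
    expect_equal(label_smoothing_loss(rep(0, C), 1, 0.37), log(C))
  # direct evaluation oracle at epsilon = 0.1, C = 5
  lg5 <- c(10, 0, 0, 0, 0)
  logp <- lg5 - log(sum(exp(lg5)))
  q <- rep(0.1 / 5, 5); q[1] <- q[1] + 0.9
  expect_equal(label_smoothing_loss(lg5, 1, 0.1), -sum(q * logp))
  expect_gt(label_smoothing_loss(c(100, -100), 1, 0.1), 0)  # strictly positive
  # permutation equivariance in the classes
  perm <- c(3, 1, 2)
  expect_equal(label_smoothing_loss(lg[perm], which(perm == 1), 0.2),
               label_smoothing_loss(lg, 1, 0.2))
  expect_error(label_smoothing_loss(lg, 1, 1), "epsilon")
  expect_error(label_smoothing_loss(lg, 4, 0.1), "out of range")
})

test_that("backpropagated gradients match finite differences", {
  ns <- asNamespace("microres")
  set.seed(22)
  spec <- backbone_spec(channel_schedule = c(4, 6), feature_dim = 5,
                        input_downsample = 1, head_channels = 8)
  model <- cropnet(c("a", "b"), backbone = spec, n_tiles = 3, seed = 7)
  pooled <- lapply(1:6, function(i) array(rnorm(8 * 8 * 3), c(8, 8, 3)))
  labels <- c(1L, 2L)
  loss_fn <- function()
    ns$cropnet_forward(model, pooled, labels = labels, epsilon = 0.1,
                       training = TRUE)$loss
  fwd <- ns$cropnet_forward(model, pooled, labels = labels, epsilon = 0.1,
                            training = TRUE)
  ns$cropnet_backward(model, fwd)
  for (L in ns$model_layers(model)) {
    if (is.null(L$params)) next
    for (nm in names(L$params)) {
      p <- L$params[[nm]]; g <- L$grads[[nm]]
      for (j in sample(length(p), min(3, length(p)))) {
        h <- 1e-5
        L$params[[nm]][j] <- p[j] + h; lp <- loss_fn()
        L$params[[nm]][j] <- p[j] - h; lm <- loss_fn()
        L$params[[nm]][j] <- p[j]
        num <- (lp - lm) / (2 * h)
        expect_equal(g[j], num, tolerance = 1e-4 + 1e-3 * abs(num))
      }
    }
  }
  # the embedding of the pyramid tile does not exist; embeddings of cropped
  # tiles receive gradient
  expect_equal(nrow(model$pos$grads$P), 2)   # n_tiles - 1
  expect_gt(sum(model$pos$grads$P^2), 0)
})

test_that("one optimizer step on a single example decreases its loss", {
  ns <- asNamespace("microres")
  set.seed(23)
  spec <- backbone_spec(channel_schedule = c(4, 6), feature_dim = 4,
                        input_downsample = 1, head_channels = 6)
  model <- cropnet(c("a", "b"), backbone = spec, n_tiles = 2, seed = 3)
  pooled <- lapply(1:2, function(i) array(rnorm(8 * 8 * 3), c(8, 8, 3)))
  fwd <- ns$cropnet_forward(model, pooled, labels = 1L, epsilon = 0.1)
  ns$cropnet_backward(model, fwd)
  st <- ns$adam_state()
  ns$adam_step(ns$model_layers(model), st, lr = 1e-4)
  fwd2 <- ns$cropnet_forward(model, pooled, labels = 1L, epsilon = 0.1)
  expect_lt(fwd2$loss, fwd$loss)
})

test_that("training fits separable data, is seeded, and no-ops at 0 epochs", {
  set.seed(24)
  mkimg <- function(cls) {
    img <- array(runif(32 * 32 * 3) * 30, c(32, 32, 3))
    if (cls == 1) img[1:12, 1:12, ] <- img[1:12, 1:12, ] + 180
    else img[21:32, 21:32, ] <- img[21:32, 21:32, ] + 180
    pmin(img, 255)
  }
  ds <- lapply(1:16, function(i)
    list(image = mkimg((i %% 2) + 1), label = c("a", "b")[(i %% 2) + 1]))
  cfg <- test_cgpo(32)
  bb <- backbone_spec(c(8, 16), feature_dim = 24, input_downsample = 2,
                      head_channels = 32)
  fit <- train_cropnet(ds, backbone = bb, cgpo = cfg,
                       config = train_config(epochs = 20, seed = 3))
  expect_equal(nrow(fit$log), 20)
  expect_equal(mean(predict(fit, ds) == sapply(ds, `[[`, "label")), 1.0)
  # determinism: same seed, same final loss
  fit2 <- train_cropnet(ds, backbone = bb, cgpo = cfg,
                        config = train_config(epochs = 20, seed = 3))
  expect_identical(fit$log$loss, fit2$log$loss)
  # zero epochs: initialized model, empty log
  fit0 <- train_cropnet(ds, backbone = bb, cgpo = cfg,
                        config = train_config(epochs = 0, seed = 3))
  expect_equal(nrow(fit0$log), 0)
  # single-class data is rejected
  expect_error(train_cropnet(ds[seq(1, 16, 2)], backbone = bb, cgpo = cfg),
               "2 classes")
})

test_that("the backbone schedule must strictly increase", {
  expect_error(backbone_spec(c(16, 16, 32)), "strictly increasing")
  expect_error(backbone_spec(c(32)), "strictly increasing")
  expect_silent(backbone_spec(c(8, 16, 24, 96)))
})
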