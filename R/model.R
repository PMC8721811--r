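# CropNet: shared increasing-channel extractor over the CGPO tiles, per-tile
# 24-d features, trainable position embeddings for the cropped tiles, additive
# fusion + concatenation, and a label-smoothing linear classifier.
#
# One extractor (shared weights) maps every tile through a strided stem
# convolution, a chain of MB6 inverted-bottleneck blocks (1x1 expand x6 ->
# depthwise 3x3 -> 1x1 project, each with batch norm), then a 1x1 convolution,
# batch norm, adaptive (global) average pooling and a fully connected layer to
# exactly 24 dimensions. The downsampled pyramid tile (index 0) carries its
# own global view and receives no position embedding; tiles 1..9 get trainable
# embeddings added elementwise before all 10 vectors are concatenated.

#' Backbone specification
#'
#' @param channel_schedule Strictly increasing stage output channels. The
#'   first entry is the stem convolution's width; each later entry adds one
#'   MB6 inverted-bottleneck block (expansion 6, stride 2).
#' @param feature_dim Per-tile feature dimension (default 24).
#' @param input_downsample Integer mean-pooling factor applied to each tile
#'   before the stem (desk-scale compute control; 1 disables).
#' @param head_channels Width of the pre-pooling 1x1 convolution; default
#'   twice the last stage.
#' @param expansion MB-block expansion ratio (default 6).
#' @return An object of class `backbone_spec`.
#' @export
backbone_spec <- function(channel_schedule = c(16, 32, 64, 96),
                          feature_dim = 24, input_downsample = 1,
                          head_channels = NULL, expansion = 6) {
  channel_schedule <- as.integer(channel_schedule)
  if (length(channel_schedule) < 2L || any(diff(channel_schedule) <= 0L))
    stop("channel_schedule must be strictly increasing with >= 2 stages")
  if (is.null(head_channels))
    head_channels <- 2L * channel_schedule[length(channel_schedule)]
  structure(list(channel_schedule = channel_schedule,
                 feature_dim = as.integer(feature_dim),
                 input_downsample = as.integer(input_downsample),
                 head_channels = as.integer(head_channels),
                 expansion = as.integer(expansion)),
            class = "backbone_spec")
}

#' Compact backbone for desk-scale experiments
#'
#' A small schedule with aggressive input pooling, sized so that full
#' leave-one-subject-out training on synthetic data runs in minutes on one CPU
#' core.
#' @return A [backbone_spec()].
#' @export
tiny_backbone <- function() {
  backbone_spec(channel_schedule = c(8, 16, 24), input_downsample = 8,
                head_channels = 48)
}

# Instantiate the layer list for a backbone spec (parameters drawn from the
# current RNG state).
build_backbone <- function(spec) {
  ch <- spec$channel_schedule
  net <- list(layer_conv(3L, ch[1], k = 3L, stride = 2L, pad = 1L),
              layer_bn(ch[1]), layer_relu())
  for (i in seq_along(ch)[-1]) {
    cin <- ch[i - 1]; cout <- ch[i]; mid <- spec$expansion * cin
    net <- c(net, list(
      layer_conv(cin, mid, k = 1L, stride = 1L, pad = 0L),
      layer_bn(mid), layer_relu(),
      layer_dwconv(mid, k = 3L, stride = 2L, pad = 1L),
      layer_bn(mid), layer_relu(),
      layer_conv(mid, cout, k = 1L, stride = 1L, pad = 0L),
      layer_bn(cout)))
  }
  c(net, list(
    layer_conv(ch[length(ch)], spec$head_channels, k = 1L, stride = 1L, pad = 0L),
    layer_bn(spec$head_channels), layer_relu(),
    layer_gap(),
    layer_fc(spec$head_channels, spec$feature_dim)))
}

#' Initialize position embeddings
#'
#' One trainable vector per cropped tile, components i.i.d. normal with mean 0
#' and variance 0.2 (standard deviation `sqrt(0.2)`).
#'
#' @param dim Embedding dimension (default 24).
#' @param count Number of embedded tiles (default 9; tile 0 is not embedded).
#' @param seed Optional seed; when given, the caller's RNG state is preserved.
#' @return A `count x dim` matrix; row i is the embedding of tile i.
#' @export
init_position_embeddings <- function(dim = 24, count = 9, seed = NULL) {
  draw <- function() matrix(stats::rnorm(count * dim, mean = 0, sd = sqrt(0.2)),
                            count, dim)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Construct an untrained CropNet
#'
#' @param classes Character vector of class names (>= 2).
#' @param backbone A [backbone_spec()].
#' @param n_tiles Number of tiles per sample (default 10 for the standard
#'   pyramid-plus-3x3-grid tiling).
#' @param seed Seed for parameter initialization.
#' @return An object of class `cropnet`.
#' @export
cropnet <- function(classes, backbone = backbone_spec(), n_tiles = 10,
                    seed = 1) {
  classes <- as.character(classes)
  if (length(classes) < 2L) stop("need at least 2 classes")
  model <- with_seed(seed, {
    net <- build_backbone(backbone)
    P <- init_position_embeddings(backbone$feature_dim, n_tiles - 1L)
    clf <- layer_fc(n_tiles * backbone$feature_dim, length(classes))
    list(net = net, pos = new_layer("pos", params = list(P = P)),
         classifier = clf)
  })
  structure(list(backbone = backbone, classes = classes,
                 n_tiles = as.integer(n_tiles),
                 net = model$net, pos = model$pos,
                 classifier = model$classifier,
                 seed = seed),
            class = "cropnet")
}

#' @export
print.cropnet <- function(x, ...) {
  cat(sprintf("<cropnet: %d tiles -> %d-d features, classes: %s>\n",
              x$n_tiles, x$backbone$feature_dim,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

# All trainable layers of a model, in a stable order.
model_layers <- function(model) c(model$net, list(model$pos, model$classifier))

# Pull tile images out of a tile_set (or accept a plain list of arrays),
# checking count and shape, and pre-pool them per the backbone spec.
tile_images <- function(tiles, model) {
  imgs <- if (inherits(tiles, "tile_set"))
    lapply(tiles$tiles, `[[`, "image") else tiles
  if (length(imgs) != model$n_tiles)
    stop("expected ", model$n_tiles, " tiles, got ", length(imgs))
  d1 <- dim(imgs[[1]])
  if (is.null(d1) || length(d1) != 3L || d1[3] != 3L)
    stop("tiles must be H x W x 3 arrays")
  if (!all(vapply(imgs, function(t) identical(dim(t), d1), logical(1))))
    stop("all tiles must share one shape")
  lapply(imgs, mean_pool_img, d = model$backbone$input_downsample)
}

# Backbone features for a stack of pre-pooled tile images (clip-major order,
# tile index fastest). Returns an (n_images x feature_dim) matrix.
backbone_features <- function(model, pooled, training = TRUE) {
  st <- net_forward(model$net, images_to_state(pooled), training = training)
  st$x
}

#' Per-tile feature vectors of one tile set
#'
#' Runs the shared extractor (evaluation mode: batch norm uses running
#' statistics) over the tiles of one sample.
#'
#' @param tiles A `tile_set` from [cgpo_tiles()] (or list of tile arrays).
#' @param model A [cropnet()].
#' @return `n_tiles x feature_dim` matrix; row i is `z_{i-1}`.
#' @export
extract_features <- function(tiles, model) {
  Z <- backbone_features(model, tile_images(tiles, model), training = FALSE)
  rownames(Z) <- paste0("z", seq_len(nrow(Z)) - 1L)
  Z
}

#' Fuse tile features with position embeddings
#'
#' `z'_i = z_i + p_i` elementwise for the cropped tiles `i >= 1`; the pyramid
#' tile `z_0` passes through unchanged. The output is the concatenation
#' `[z_0, z'_1, ..., z'_k]` in tile order.
#'
#' @param z `n_tiles x d` matrix of tile features (row 1 is `z_0`).
#' @param p `(n_tiles - 1) x d` matrix of position embeddings.
#' @return Numeric vector of length `n_tiles * d`.
#' @export
fuse <- function(z, p) {
  if (!identical(dim(p) + c(1L, 0L), dim(z)))
    stop("embedding shape ", paste(dim(p), collapse = "x"),
         " does not match features ", paste(dim(z), collapse = "x"))
  zp <- z
  zp[-1L, ] <- z[-1L, , drop = FALSE] + p
  as.vector(t(zp))
}

#' Label-smoothing cross-entropy
#'
#' `loss = -sum_k q_k log softmax(logits)_k` with
#' `q_k = (1 - epsilon) 1[k = true] + epsilon / C`. At `epsilon = 0` this is
#' ordinary cross-entropy.
#'
#' @param logits Numeric vector of length C.
#' @param true_class 1-based index of the true class.
#' @param epsilon Smoothing mass in `[0, 1)`.
#' @return Non-negative scalar.
#' @export
label_smoothing_loss <- function(logits, true_class, epsilon = 0.1) {
  if (epsilon < 0 || epsilon >= 1) stop("epsilon must be in [0, 1)")
  C <- length(logits)
  if (true_class < 1 || true_class > C) stop("true_class out of range")
  logp <- logits - logsumexp(logits)
  q <- rep(epsilon / C, C)
  q[true_class] <- q[true_class] + (1 - epsilon)
  -sum(q * logp)
}

logsumexp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

# Batched forward pass over pooled tile stacks. labels: integer class indices
# (1-based) per clip, or NULL for prediction. Returns logits and, with labels,
# the mean smoothed loss and the gradient hook inputs.
cropnet_forward <- function(model, pooled, labels = NULL, epsilon = 0.1,
                            training = TRUE) {
  nt <- model$n_tiles
  d <- model$backbone$feature_dim
  B <- length(pooled) %/% nt
  Z <- backbone_features(model, pooled, training = training)
  Pmat <- rbind(0, model$pos$params$P)                 # n_tiles x d, row 1 = 0
  Zp <- Z + Pmat[rep(seq_len(nt), B), , drop = FALSE]
  Fm <- matrix(as.vector(t(Zp)), nrow = B, byrow = TRUE)  # B x (nt * d)
  stf <- act_state(Fm, 1L, 1L, B)
  logits <- layer_forward(model$classifier, stf, training)$x
  out <- list(logits = logits, B = B)
  if (!is.null(labels)) {
    C <- length(model$classes)
    m <- apply(logits, 1, max)
    ls <- logits - m
    logp <- ls - log(rowSums(exp(ls)))
    q <- matrix(epsilon / C, B, C)
    q[cbind(seq_len(B), labels)] <- q[cbind(seq_len(B), labels)] + (1 - epsilon)
    out$loss <- -mean(rowSums(q * logp))
    out$dlogits <- (exp(logp) - q) / B
  }
  out
}

# Backward pass matching cropnet_forward(training = TRUE). Sets grads on all
# layers (including position embeddings).
cropnet_backward <- function(model, fwd) {
  nt <- model$n_tiles
  B <- fwd$B
  dstf <- layer_backward(model$classifier, act_state(fwd$dlogits, 1L, 1L, B))
  dZp <- matrix(as.vector(t(dstf$x)), ncol = model$backbone$feature_dim,
                byrow = TRUE)                           # (B * nt) x d
  dP <- rowsum(dZp, rep(seq_len(nt), B))
  model$pos$grads <- list(P = dP[-1L, , drop = FALSE])
  net_backward(model$net, act_state(dZp, 1L, 1L, B * nt))
  invisible(model)
}

#' Training configuration
#'
#' @param epochs Number of passes over the training set.
#' @param lr Adam learning rate.
#' @param batch_size Clips per minibatch (`Inf` = full batch).
#' @param epsilon Label-smoothing mass.
#' @param seed RNG seed covering initialization, shuffling and augmentation.
#' @param augment `NULL` to train on the deterministic tiles, or an
#'   [augment_config()] applied to each residual image every epoch before
#'   tiling.
#' @param verbose Print per-epoch loss.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 40, lr = 3e-3, batch_size = 12,
                         epsilon = 0.1, seed = 1, augment = NULL,
                         verbose = FALSE) {
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = batch_size, epsilon = epsilon,
                 seed = as.integer(seed), augment = augment,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

sample_image <- function(s) if (inherits(s$image, "residual_image")) s$image$pixels else s$image

#' Train a CropNet on preprocessed images
#'
#' Runs the augment -> tile -> extract -> fuse -> classify graph under the
#' label-smoothing loss with Adam. Deterministic given the seed (single
#' threaded). With `epochs = 0` the initialized model is returned unchanged.
#'
#' @param dataset List of samples, each a list with `image` (a
#'   `residual_image` or H x W x 3 array) and `label` (class string).
#' @param classes Ordered class vector; defaults to the sorted labels present.
#' @param model A [cropnet()], or `NULL` to initialize one from
#'   `backbone`/`config$seed`.
#' @param backbone A [backbone_spec()] used when `model` is NULL.
#' @param config A [train_config()].
#' @param cgpo A [cgpo_config()].
#' @return A list of class `cropnet_fit`: `model`, `classes`, `log`
#'   (data.frame epoch/loss), `config`.
#' @export
train_cropnet <- function(dataset, classes = NULL, model = NULL,
                          backbone = backbone_spec(), config = train_config(),
                          cgpo = cgpo_config()) {
  labels <- vapply(dataset, function(s) s$label, character(1))
  if (is.null(classes)) classes <- sort(unique(labels))
  if (length(unique(labels)) < 2L)
    stop("training requires at least 2 classes, got ",
         length(unique(labels)))
  if (!all(labels %in% classes)) stop("labels outside the class set")
  y <- match(labels, classes)
  set.seed(config$seed)
  if (is.null(model))
    model <- cropnet(classes, backbone = backbone, seed = config$seed)
  n <- length(dataset)
  images <- lapply(dataset, sample_image)
  tile_stack <- function(imgs) {
    pooled <- vector("list", n * model$n_tiles)
    for (i in seq_len(n)) {
      ts <- tile_images(cgpo_tiles(imgs[[i]], cgpo), model)
      pooled[(i - 1L) * model$n_tiles + seq_len(model$n_tiles)] <- ts
    }
    pooled
  }
  static_pool <- if (is.null(config$augment)) tile_stack(images) else NULL
  opt <- adam_state()
  log <- data.frame(epoch = integer(0), loss = numeric(0))
  bs <- if (is.finite(config$batch_size)) as.integer(config$batch_size) else n
  for (epoch in seq_len(config$epochs)) {
    pooled <- if (is.null(static_pool))
      tile_stack(lapply(images, augment_image, config = config$augment))
    else static_pool
    ord <- sample.int(n)
    total <- 0
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      tix <- as.vector(vapply(idx, function(i)
        (i - 1L) * model$n_tiles + seq_len(model$n_tiles),
        integer(model$n_tiles)))
      fwd <- cropnet_forward(model, pooled[tix], labels = y[idx],
                             epsilon = config$epsilon, training = TRUE)
      cropnet_backward(model, fwd)
      adam_step(model_layers(model), opt, lr = config$lr)
      total <- total + fwd$loss * length(idx)
    }
    log <- rbind(log, data.frame(epoch = epoch, loss = total / n))
    if (config$verbose)
      message(sprintf("epoch %3d  loss %.4f", epoch, total / n))
  }
  structure(list(model = model, classes = classes, log = log,
                 config = config, cgpo = cgpo),
            class = "cropnet_fit")
}

#' Predict classes for preprocessed images
#'
#' @param object A `cropnet_fit` from [train_cropnet()].
#' @param newdata List of samples (as in [train_cropnet()]) or of plain
#'   images.
#' @param type `"class"` (default) or `"prob"` (softmax matrix).
#' @param ... Unused.
#' @return Character vector of predicted classes, or a probability matrix.
#' @export
predict.cropnet_fit <- function(object, newdata, type = c("class", "prob"),
                                ...) {
  type <- match.arg(type)
  model <- object$model
  imgs <- lapply(newdata, function(s)
    if (is.list(s) && !is.null(s$image)) sample_image(s) else s)
  pooled <- unlist(lapply(imgs, function(im)
    tile_images(cgpo_tiles(im, object$cgpo), model)), recursive = FALSE)
  fwd <- cropnet_forward(model, pooled, training = FALSE)
  pr <- exp(fwd$logits - apply(fwd$logits, 1, logsumexp))
  colnames(pr) <- object$classes
  if (type == "prob") return(pr)
  object$classes[max.col(pr, ties.method = "first")]
}
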