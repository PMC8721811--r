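# End-to-end pipeline: window -> key frames -> face crop -> residual image per
# clip, then leave-one-subject-out training/evaluation with pooled scoring.

#' Preprocess one clip into a single image
#'
#' Selects the analysis window and key frames, crops the face with one box
#' computed from the clip's landmarks (applied to every frame so crop jitter
#' cannot masquerade as motion), and collapses the window into an ARS or RRS
#' residual image — or the raw apex frame for the baseline method.
#'
#' @param clip A `clip`.
#' @param landmarks 68 x 2 landmark matrix; defaults to the clip's
#'   `landmarks` attribute.
#' @param method `"rrs"`, `"ars"` or `"apex"`.
#' @param n_key Number of key frames.
#' @param margin Face-box margin fraction.
#' @param output_size Side of the cropped, resampled image (default 320, the
#'   tiling input resolution).
#' @param gmin,gmax RRS output range.
#' @return A `residual_image`.
#' @export
preprocess_clip <- function(clip, landmarks = NULL,
                            method = c("rrs", "ars", "apex"), n_key = 5,
                            margin = 0.1, output_size = 320,
                            gmin = 0, gmax = 255) {
  method <- match.arg(method)
  if (is.null(landmarks)) landmarks <- attr(clip, "landmarks")
  if (is.null(landmarks))
    stop("clip ", clip$annotation$clip_id, ": no landmarks available")
  spec <- landmarks_to_box(landmarks, margin = margin,
                           frame_shape = dim(clip$frames[[1]]),
                           output_size = c(output_size, output_size))
  if (method == "apex") {
    ai <- resolve_apex(clip$annotation)
    img <- crop_and_resize(clip_frame(clip, ai), spec)
    return(new_residual_image(img, "APEX"))
  }
  w <- select_window(clip$annotation)
  kf <- select_keyframes(w["start"], w["end"], n_key)
  # crop only the frames the residual needs, remapped to local indices
  need <- sort(unique(c(kf$start, kf$frames)))
  cropped <- crop_clip(clip, spec, indices = need)
  remap <- function(i) match(i, need) - 1L
  kf_local <- kf
  kf_local$start <- remap(kf$start)
  kf_local$frames <- vapply(kf$frames, remap, integer(1))
  if (method == "ars") ars_image(cropped, kf_local)
  else rrs_image(cropped, kf_local, gmin = gmin, gmax = gmax)
}

#' Preprocess a corpus of clips
#'
#' @param clips List of `clip` objects (e.g. from [generate_dataset()] or
#'   [read_clip()]).
#' @param landmarks Optional list of landmark matrices parallel to `clips`.
#' @param ... Passed to [preprocess_clip()].
#' @return List of samples `list(image, label, subject, clip_id)` ready for
#'   [train_cropnet()] / [run_loso()].
#' @export
preprocess_dataset <- function(clips, landmarks = NULL, ...) {
  lapply(seq_along(clips), function(i) {
    cl <- clips[[i]]
    lm <- if (is.null(landmarks)) NULL else landmarks[[i]]
    img <- tryCatch(
      preprocess_clip(cl, landmarks = lm, ...),
      error = function(e) stop("preprocess failed for clip ",
                               cl$annotation$clip_id, ": ",
                               conditionMessage(e), call. = FALSE))
    list(image = img, label = cl$annotation$label,
         subject = cl$annotation$subject_id,
         clip_id = cl$annotation$clip_id)
  })
}

#' Leave-one-subject-out training and pooled evaluation
#'
#' Trains one model per fold on all other subjects' samples and predicts the
#' held-out subject's. Predictions are pooled across folds before UF1 / UAR /
#' accuracy are computed once (composite convention).
#'
#' @param samples List of samples as produced by [preprocess_dataset()].
#' @param classes Ordered class vector; default sorted unique labels.
#' @param backbone A [backbone_spec()].
#' @param config A [train_config()]; each fold derives its seed from
#'   `config$seed`.
#' @param cgpo A [cgpo_config()].
#' @param verbose Print per-fold progress.
#' @return List with the pooled [evaluation_report()] fields plus `folds`
#'   (per-fold subject, test size, correct count) and `predictions`
#'   (data.frame subject/clip/true/pred).
#' @export
run_loso <- function(samples, classes = NULL, backbone = tiny_backbone(),
                     config = train_config(), cgpo = cgpo_config(),
                     verbose = FALSE) {
  labels <- vapply(samples, `[[`, character(1), "label")
  if (is.null(classes)) classes <- sort(unique(labels))
  anns <- lapply(samples, function(s) list(subject_id = s$subject))
  folds <- loso_splits(anns)
  pred <- character(length(samples))
  fold_rows <- list()
  for (k in seq_along(folds)) {
    fo <- folds[[k]]
    cfg <- config
    cfg$seed <- config$seed + k
    fit <- train_cropnet(samples[fo$train], classes = classes,
                         backbone = backbone, config = cfg, cgpo = cgpo)
    pred[fo$test] <- predict(fit, samples[fo$test])
    correct <- sum(pred[fo$test] == labels[fo$test])
    fold_rows[[k]] <- data.frame(subject = fo$subject,
                                 n_test = length(fo$test),
                                 n_correct = correct)
    if (verbose)
      message(sprintf("fold %s: %d/%d correct", fo$subject, correct,
                      length(fo$test)))
  }
  rep <- evaluation_report(labels, pred, classes)
  rep$folds <- do.call(rbind, fold_rows)
  rep$predictions <- data.frame(
    subject = vapply(samples, `[[`, character(1), "subject"),
    clip = vapply(samples, `[[`, character(1), "clip_id"),
    true = labels, pred = pred)
  rep
}

#' Run the full pipeline on a synthetic corpus
#'
#' Generates clips, preprocesses them with the requested method, runs
#' leave-one-subject-out evaluation, and optionally writes the JSON report and
#' confusion CSV.
#'
#' @param synth A [synth_config()].
#' @param method Preprocessing method (`"rrs"`, `"ars"`, `"apex"`).
#' @param backbone,train,cgpo Module configurations.
#' @param out_dir Optional output directory for `report.json` and
#'   `confusion.csv`.
#' @param verbose Print progress.
#' @return The [run_loso()] report.
#' @export
run_pipeline <- function(synth = synth_config(), method = "rrs",
                         backbone = tiny_backbone(), train = train_config(),
                         cgpo = cgpo_config(), out_dir = NULL,
                         verbose = FALSE) {
  samples <- synth_samples(synth, methods = method)[[method]]
  rep <- run_loso(samples, backbone = backbone, config = train, cgpo = cgpo,
                  verbose = verbose)
  if (!is.null(out_dir)) write_report(rep, out_dir)
  rep
}

#' Write an evaluation report to disk
#'
#' `report.json` holds the scalar metrics, per-class scores and fold table;
#' `confusion.csv` the confusion matrix (rows = true classes).
#'
#' @param rep A [run_loso()] report.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(rep, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(uf1 = rep$uf1, uar = rep$uar, accuracy = rep$accuracy,
         per_class_f1 = as.list(rep$per_class_f1),
         per_class_recall = as.list(rep$per_class_recall),
         folds = rep$folds),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  utils::write.csv(rep$confusion$matrix, file.path(out_dir, "confusion.csv"))
  invisible(out_dir)
}

#' Read a corpus from disk
#'
#' Expects the layout written by [write_synth_dataset()]: frame directories
#' named `<subject>_<clip>`, an `annotations.csv` and per-clip landmark CSVs
#' under `landmarks/`.
#'
#' @param data_dir Corpus directory.
#' @param index_base Frame-index convention of the annotation file.
#' @return List of `clip` objects with `landmarks` attributes.
#' @export
read_dataset <- function(data_dir, index_base = 0) {
  if (!dir.exists(data_dir)) stop("data directory not found: ", data_dir)
  anns <- read_annotations(file.path(data_dir, "annotations.csv"),
                           index_base = index_base)
  lapply(anns, function(a) {
    stem <- paste0(a$subject_id, "_", a$clip_id)
    cl <- read_clip(file.path(data_dir, stem), a)
    lm_path <- file.path(data_dir, "landmarks", paste0(stem, ".csv"))
    if (file.exists(lm_path)) attr(cl, "landmarks") <- read_landmarks(lm_path)
    cl
  })
}
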