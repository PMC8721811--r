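# Evaluation protocol: per-class confusion counts, UF1 (macro F1), UAR
# (balanced accuracy), plain accuracy, and leave-one-subject-out splitting
# with pooled composite scoring (MEGC2019 convention: predictions from all
# folds are pooled before computing the metrics once).

#' Per-class confusion counts
#'
#' @param true_labels,pred_labels Equal-length vectors of labels drawn from
#'   `classes`.
#' @param classes Ordered class vector; defaults to the sorted union of the
#'   labels.
#' @return An object of class `confusion_counts`: per-class `tp`, `fp`, `fn`,
#'   `n` vectors, class count `C`, total `N`, and the full confusion `matrix`
#'   (rows = true, columns = predicted).
#' @export
confusion <- function(true_labels, pred_labels, classes = NULL) {
  if (length(true_labels) == 0L) stop("empty label vectors")
  if (length(true_labels) != length(pred_labels))
    stop("true and predicted label vectors differ in length")
  if (is.null(classes)) classes <- sort(unique(c(true_labels, pred_labels)))
  if (!all(true_labels %in% classes) || !all(pred_labels %in% classes))
    stop("labels outside the class set: ",
         paste(setdiff(unique(c(true_labels, pred_labels)), classes),
               collapse = ", "))
  tf <- factor(true_labels, levels = classes)
  pf <- factor(pred_labels, levels = classes)
  m <- table(true = tf, predicted = pf)
  tp <- diag(m)
  structure(list(tp = as.numeric(tp),
                 fp = as.numeric(colSums(m) - tp),
                 fn = as.numeric(rowSums(m) - tp),
                 n = as.numeric(rowSums(m)),
                 C = length(classes), N = length(true_labels),
                 classes = classes, matrix = unclass(m)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts over", x$N, "examples,", x$C, "classes>\n")
  print(x$matrix)
  invisible(x)
}

#' Unweighted F1 (macro-averaged F1)
#'
#' `UF1 = (1/C) * sum_i 2 TP_i / (2 TP_i + FP_i + FN_i)`. A class that never
#' occurs and is never predicted has an indeterminate (0/0) F1 term; it
#' contributes 0 and is reported in the `absent_classes` attribute.
#'
#' @param counts A [confusion()] result.
#' @return Scalar in `[0, 1]`.
#' @export
uf1 <- function(counts) {
  if (counts$C == 0L) stop("no classes")
  denom <- 2 * counts$tp + counts$fp + counts$fn
  terms <- ifelse(denom > 0, 2 * counts$tp / denom, 0)
  structure(mean(terms), absent_classes = counts$classes[denom == 0])
}

#' Unweighted average recall (balanced accuracy)
#'
#' `UAR = (1/C) * sum_i TP_i / N_i`. Undefined (an error) if any class has no
#' true examples.
#'
#' @param counts A [confusion()] result.
#' @return Scalar in `[0, 1]`.
#' @export
uar <- function(counts) {
  if (any(counts$n == 0))
    stop("UAR undefined: class(es) with zero support: ",
         paste(counts$classes[counts$n == 0], collapse = ", "))
  mean(counts$tp / counts$n)
}

#' Overall accuracy
#'
#' `sum_i TP_i / N`.
#' @param counts A [confusion()] result.
#' @return Scalar in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  if (counts$N == 0L) stop("no examples")
  sum(counts$tp) / counts$N
}

#' Leave-one-subject-out folds
#'
#' One fold per subject, ordered by subject id: the fold's test set is that
#' subject's clips and the training set is everything else. Test sets
#' partition the clips.
#'
#' @param annotations List of [clip_annotation()]s (or any list of objects
#'   with `subject_id` fields).
#' @return List of folds, each `list(subject, train, test)` with `train`/`test`
#'   integer indices into `annotations`.
#' @export
loso_splits <- function(annotations) {
  subjects <- vapply(annotations, function(a) a$subject_id, character(1))
  ids <- sort(unique(subjects))
  if (length(ids) < 2L)
    stop("leave-one-subject-out needs >= 2 subjects, got ", length(ids))
  lapply(ids, function(s)
    list(subject = s,
         train = which(subjects != s),
         test = which(subjects == s)))
}

#' Pooled evaluation report
#'
#' Computes UF1, UAR and accuracy once over pooled predictions (composite /
#' MEGC2019 convention), plus per-class F1 and recall.
#'
#' @param true_labels,pred_labels Pooled label vectors.
#' @param classes Ordered class vector.
#' @return List with `uf1`, `uar`, `accuracy`, `per_class_f1`,
#'   `per_class_recall`, `confusion`.
#' @export
evaluation_report <- function(true_labels, pred_labels, classes = NULL) {
  cc <- confusion(true_labels, pred_labels, classes)
  denom <- 2 * cc$tp + cc$fp + cc$fn
  f1 <- ifelse(denom > 0, 2 * cc$tp / denom, 0)
  rec <- ifelse(cc$n > 0, cc$tp / cc$n, NA_real_)
  names(f1) <- names(rec) <- cc$classes
  list(uf1 = as.numeric(uf1(cc)), uar = uar(cc), accuracy = accuracy(cc),
       per_class_f1 = f1, per_class_recall = rec, confusion = cc)
}
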