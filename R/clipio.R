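# Clip, annotation and landmark I/O.
#
# A clip is a directory of numbered 8-bit RGB frame images plus one row of an
# annotation table giving subject, clip id, onset/apex/offset frame indices and
# an emotion label. Frame indices are 0-based positions in the clip's sorted
# file list; annotation files written with 1-based dataset conventions are
# converted at ingest via `index_base = 1`.

#' Construct a clip annotation
#'
#' Holds a clip's identity, its onset/apex/offset frame indices and its emotion
#' label. The apex may be absent (`NA`), as in SMIC-HS, in which case
#' [resolve_apex()] falls back to the clip midpoint.
#'
#' @param subject_id,clip_id Character scalars identifying the subject and clip.
#' @param onset,offset Integer frame indices, `0 <= onset <= offset`.
#' @param apex Integer frame index with `onset <= apex <= offset`, or `NA`.
#' @param label Emotion-class string (e.g. `"happiness"`, `"negative"`).
#' @return An object of class `clip_annotation`.
#' @export
clip_annotation <- function(subject_id, clip_id, onset, apex, offset, label) {
  onset <- as.integer(onset)
  offset <- as.integer(offset)
  apex <- if (length(apex) == 0 || is.na(apex)) NA_integer_ else as.integer(apex)
  if (is.na(onset) || is.na(offset) || onset < 0L)
    stop("clip ", clip_id, ": onset/offset must be non-negative integers")
  if (onset > offset)
    stop("clip ", clip_id, ": onset (", onset, ") > offset (", offset, ")")
  if (!is.na(apex) && (apex < onset || apex > offset))
    stop("clip ", clip_id, ": apex (", apex, ") outside [onset, offset]")
  structure(
    list(subject_id = as.character(subject_id), clip_id = as.character(clip_id),
         onset = onset, apex = apex, offset = offset, label = as.character(label)),
    class = "clip_annotation")
}

#' @export
print.clip_annotation <- function(x, ...) {
  cat(sprintf("<clip_annotation %s/%s onset=%d apex=%s offset=%d label=%s>\n",
              x$subject_id, x$clip_id, x$onset,
              ifelse(is.na(x$apex), "-", x$apex), x$offset, x$label))
  invisible(x)
}

#' Read an annotation table
#'
#' Expects a UTF-8 CSV with header columns `subject,clip,onset,apex,offset,label`.
#' An empty `apex` field marks an unlabelled apex (`NA`).
#'
#' @param csv_path Path to the CSV file.
#' @param index_base 0 or 1: the index convention used by the file. Indices are
#'   converted to the package's 0-based convention.
#' @return A list of [clip_annotation()] objects.
#' @export
read_annotations <- function(csv_path, index_base = 0) {
  if (!file.exists(csv_path)) stop("annotation file not found: ", csv_path)
  stopifnot(index_base %in% c(0, 1))
  df <- utils::read.csv(csv_path, colClasses = "character", strip.white = TRUE)
  need <- c("subject", "clip", "onset", "apex", "offset", "label")
  if (!all(need %in% names(df)))
    stop("annotation CSV must have columns ", paste(need, collapse = ","))
  parse_idx <- function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_integer_)
    v <- suppressWarnings(as.integer(s))
    if (is.na(v)) stop("non-integer frame index '", s, "'")
    v
  }
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    tryCatch(
      clip_annotation(row$subject, row$clip,
                      onset = parse_idx(row$onset) - index_base,
                      apex = {
                        a <- parse_idx(row$apex)
                        if (is.na(a)) a else a - index_base
                      },
                      offset = parse_idx(row$offset) - index_base,
                      label = row$label),
      error = function(e) stop("annotation row ", i, ": ", conditionMessage(e),
                               call. = FALSE))
  })
}

#' Write an annotation table
#'
#' @param annotations List of [clip_annotation()] objects.
#' @param csv_path Output path.
#' @param index_base Index convention to write (0 or 1).
#' @export
write_annotations <- function(annotations, csv_path, index_base = 0) {
  df <- do.call(rbind, lapply(annotations, function(a) {
    data.frame(subject = a$subject_id, clip = a$clip_id,
               onset = a$onset + index_base,
               apex = if (is.na(a$apex)) "" else a$apex + index_base,
               offset = a$offset + index_base, label = a$label)
  }))
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  invisible(csv_path)
}

# Read one frame image as an H x W x 3 array of 0..255 values.
read_frame <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      stop("reading JPEG frames requires the 'jpeg' package; convert to PNG")
    img <- jpeg::readJPEG(path)
  } else stop("unsupported frame format: ", path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  round(img * 255)
}

# Write an H x W x 3 array of 0..255 values as PNG (bit-exact round trip).
write_frame <- function(frame, path) {
  png::writePNG(clamp01(frame / 255), path)
  invisible(path)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Read a clip from a frame directory
#'
#' Frames are PNG (or JPEG, if the `jpeg` package is installed) files with
#' numeric names; they are ordered by their numeric value, so `frame_0.png`,
#' zero-padded and unpadded names all sort correctly. All frames must share one
#' shape, and the annotation's indices must address existing frames.
#'
#' @param frame_dir Directory containing the frame images.
#' @param annotation A [clip_annotation()].
#' @return An object of class `clip`: list with `annotation` and `frames`
#'   (list of H x W x 3 arrays with values in 0..255).
#' @export
read_clip <- function(frame_dir, annotation) {
  cid <- annotation$clip_id
  if (!dir.exists(frame_dir))
    stop("clip ", cid, ": frame directory not found: ", frame_dir)
  files <- list.files(frame_dir, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE)
  if (length(files) == 0L) stop("clip ", cid, ": no frame images in ", frame_dir)
  num <- suppressWarnings(as.numeric(gsub("[^0-9]", "", sub("\\.[^.]+$", "", files))))
  if (anyNA(num)) stop("clip ", cid, ": frame filenames must contain a number")
  files <- files[order(num)]
  frames <- lapply(file.path(frame_dir, files), read_frame)
  shp <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), shp), logical(1))))
    stop("clip ", cid, ": inconsistent frame shape across ", frame_dir)
  if (annotation$offset >= length(frames))
    stop("clip ", cid, ": offset out of range (", annotation$offset,
         " >= ", length(frames), " frames)")
  new_clip(annotation, frames)
}

new_clip <- function(annotation, frames) {
  structure(list(annotation = annotation, frames = frames), class = "clip")
}

#' @export
print.clip <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<clip %s/%s: %d frames of %dx%dx%d, label=%s>\n",
              x$annotation$subject_id, x$annotation$clip_id, length(x$frames),
              d[1], d[2], d[3], x$annotation$label))
  invisible(x)
}

#' Write a clip's frames to a directory as PNG
#'
#' @param clip A `clip` object.
#' @param frame_dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_clip <- function(clip, frame_dir) {
  dir.create(frame_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(clip$frames))
    write_frame(clip$frames[[i]], file.path(frame_dir, sprintf("%04d.png", i - 1L)))
  invisible(frame_dir)
}

#' Resolve a clip's apex frame
#'
#' Returns the annotated apex when present; otherwise the floor midpoint of
#' `[onset, offset]`, generalizing the mid-frame convention used for apex-less
#' SMIC-HS clips.
#'
#' @param annotation A [clip_annotation()].
#' @return An integer frame index.
#' @export
resolve_apex <- function(annotation) {
  if (!is.na(annotation$apex)) return(annotation$apex)
  as.integer((annotation$onset + annotation$offset) %/% 2L)
}

# Source classes mappable under the MEGC2019 composite (CDE) protocol.
.cde_map <- c(
  disgust = "negative", contempt = "negative", fear = "negative",
  sadness = "negative", anger = "negative", negative = "negative",
  happiness = "positive", positive = "positive",
  surprise = "surprise")

#' Merge emotion labels to the MEGC2019 three-class scheme
#'
#' The composite-dataset evaluation protocol maps disgust, contempt, fear,
#' sadness and anger to `negative`, happiness to `positive`, and keeps
#' `surprise`. Labels outside the nine mappable source classes (e.g. "others",
#' "repression") are rejected.
#'
#' @param label Character vector of source-class names (case-insensitive).
#' @return Character vector over `{negative, positive, surprise}`.
#' @export
merge_to_three_classes <- function(label) {
  key <- tolower(trimws(label))
  out <- .cde_map[key]
  if (anyNA(out))
    stop("label(s) not mappable under CDE protocol: ",
         paste(unique(label[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Read a 68-point landmark file
#'
#' A landmark CSV has columns `x,y` and 68 rows (a single reference frame), in
#' pixel units.
#'
#' @param csv_path Path to the CSV.
#' @return A 68 x 2 numeric matrix with columns `x`, `y`.
#' @export
read_landmarks <- function(csv_path) {
  if (!file.exists(csv_path)) stop("landmark file not found: ", csv_path)
  df <- utils::read.csv(csv_path)
  if (!all(c("x", "y") %in% names(df))) stop("landmark CSV needs columns x,y")
  as_landmarks(cbind(x = df$x, y = df$y))
}

#' @rdname read_landmarks
#' @param landmarks 68 x 2 matrix of landmark coordinates.
#' @export
write_landmarks <- function(landmarks, csv_path) {
  utils::write.csv(data.frame(x = landmarks[, 1], y = landmarks[, 2]),
                   csv_path, row.names = FALSE)
  invisible(csv_path)
}

as_landmarks <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != 68L || ncol(m) != 2L)
    stop("expected 68 landmark points (x, y); got ", nrow(m), " x ", ncol(m))
  colnames(m) <- c("x", "y")
  m
}
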