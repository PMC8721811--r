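test_that("clip round-trips through PNG bit-exactly", {
  cl <- random_clip(4, h = 6, w = 5)
  dir <- withr::local_tempdir()
  write_clip(cl, dir)
  back <- read_clip(dir, cl$annotation)
  expect_length(back$frames, 4)
  expect_identical(back$frames, cl$frames)
})

test_that("read_clip validates shapes and annotation indices", {
  dir <- withr::local_tempdir()
  microres:::write_frame(array(1, c(4, 4, 3)), file.path(dir, "000.png"))
  microres:::write_frame(array(1, c(5, 4, 3)), file.path(dir, "001.png"))
  ann <- clip_annotation("s", "bad", 0, NA, 1, "x")
  expect_error(read_clip(dir, ann), "inconsistent frame shape")

  dir2 <- withr::local_tempdir()
  for (i in 0:2)
    microres:::write_frame(array(0, c(4, 4, 3)),
                           file.path(dir2, sprintf("%03d.png", i)))
  expect_error(read_clip(dir2, clip_annotation("s", "c9", 0, NA, 40, "x")),
               "offset out of range")
  expect_error(read_clip(file.path(dir2, "missing"),
                         clip_annotation("s", "c1", 0, NA, 1, "x")),
               "not found")
})

test_that("annotation CSV parsing handles apex absence and rejects bad rows", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,clip,onset,apex,offset,label",
               "s01,c01,5,12,30,happiness",
               "s01,c02,0,,20,negative"), p)
  anns <- read_annotations(p)
  expect_length(anns, 2)
  expect_equal(anns[[1]]$onset, 5)
  expect_equal(anns[[1]]$apex, 12)
  expect_equal(anns[[1]]$offset, 30)
  expect_true(is.na(anns[[2]]$apex))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,clip,onset,apex,offset,label",
               "s01,c03,10,5,20,x"), bad)
  expect_error(read_annotations(bad), "row 1")

  one <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,clip,onset,apex,offset,label",
               "s01,c01,6,13,31,happiness"), one)
  expect_equal(read_annotations(one, index_base = 1)[[1]]$onset, 5)
})

test_that("annotation round-trips through CSV", {
  anns <- list(clip_annotation("s01", "c01", 2, 9, 19, "surprise"),
               clip_annotation("s02", "c01", 0, NA, 11, "negative"))
  p <- withr::local_tempfile(fileext = ".csv")
  write_annotations(anns, p)
  back <- read_annotations(p)
  expect_equal(back, anns)
})

test_that("CDE merging covers the nine source classes and is idempotent", {
  src <- c("disgust", "contempt", "fear", "sadness", "anger", "negative",
           "happiness", "positive", "surprise")
  merged <- merge_to_three_classes(src)
  expect_equal(merged[1:6], rep("negative", 6))
  expect_equal(merged[7:8], rep("positive", 2))
  expect_equal(merged[9], "surprise")
  # idempotent on its own outputs, case-insensitive on input
  expect_equal(merge_to_three_classes(merged), merged)
  expect_equal(merge_to_three_classes("Anger"), "negative")
  expect_error(merge_to_three_classes("repression"), "CDE")
  expect_error(merge_to_three_classes("others"), "CDE")
})

test_that("apex resolution falls back to the floor midpoint", {
  expect_equal(resolve_apex(clip_annotation("s", "c", 0, 12, 30, "x")), 12)
  expect_equal(resolve_apex(clip_annotation("s", "c", 0, NA, 30, "x")), 15)
  expect_equal(resolve_apex(clip_annotation("s", "c", 7, NA, 8, "x")), 7)
})

test_that("annotation invariants are enforced at construction", {
  expect_error(clip_annotation("s", "c", 10, 5, 20, "x"), "apex")
  expect_error(clip_annotation("s", "c", 21, NA, 20, "x"), "onset")
  expect_silent(clip_annotation("s", "c", 5, 5, 5, "x"))
})

test_that("landmark files round-trip", {
  lm <- cbind(x = runif(68, 0, 100), y = runif(68, 0, 120))
  p <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(lm, p)
  expect_equal(unname(read_landmarks(p)), unname(lm))
  expect_error(microres:::as_landmarks(lm[1:10, ]), "68")
})
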