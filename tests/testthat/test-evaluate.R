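test_that("box IoU matches direct area arithmetic", {
  expect_equal(box_iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(box_iou(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0)
  expect_equal(box_iou(c(0, 0, 10, 10), c(5, 0, 15, 10)), 1 / 3)
  expect_error(box_iou(c(0, 0, 0, 10), c(0, 0, 5, 5)), "degenerate")
})

test_that("greedy matching picks the globally best pairs one-to-one", {
  pred <- tibble::tibble(rmin = 0, cmin = 0, rmax = 10, cmax = 10)
  truth_eq <- pred
  m <- match_boxes(pred, truth_eq)
  expect_equal(nrow(m), 1)
  expect_equal(m$iou, 1)

  # one prediction overlapping two truths: matched to the higher IoU
  truths <- tibble::tibble(rmin = c(0, 0), cmin = c(2, 7),
                           rmax = c(10, 10), cmax = c(12, 17))
  m2 <- match_boxes(pred, truths)
  expect_equal(nrow(m2), 1)
  expect_equal(m2$truth, 1)

  # all pairs below threshold: no matches
  far <- tibble::tibble(rmin = 9, cmin = 9, rmax = 40, cmax = 40)
  expect_equal(nrow(match_boxes(pred, far, iou_threshold = 0.10)), 0)
})

test_that("greedy matching agrees with the exhaustive oracle on small instances", {
  set.seed(77)
  for (i in 1:60) {
    preds <- random_boxes(sample(1:6, 1))
    truths <- random_boxes(sample(1:6, 1))
    got <- sort(match_boxes(preds, truths)$iou, decreasing = TRUE)
    want <- brute_force_match_seq(preds, truths)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("raising the IoU threshold never increases matches; roles are symmetric", {
  set.seed(78)
  preds <- random_boxes(8)
  truths <- random_boxes(8)
  ns <- vapply(c(0.05, 0.1, 0.3, 0.6, 0.9), function(thr) {
    nrow(match_boxes(preds, truths, thr))
  }, 0)
  expect_true(all(diff(ns) <= 0))

  a <- match_boxes(preds, truths)
  b <- match_boxes(truths, preds)
  expect_equal(sort(a$iou), sort(b$iou))
  expect_equal(nrow(a), nrow(b))
})

test_that("confusion matrix keeps every box exactly once", {
  set.seed(79)
  preds <- dplyr::mutate(random_boxes(10),
                         label = sample(c("NET", "PMN", "Unknown"), 10,
                                        replace = TRUE))
  truths <- dplyr::mutate(random_boxes(7),
                          label = sample(c("NET", "PMN"), 7, replace = TRUE))
  pairs <- match_boxes(preds, truths)
  rep <- confusion_and_stats(pairs, preds, truths)
  expect_equal(sum(rep$confusion),
               nrow(preds) + nrow(truths) - nrow(pairs))
})

test_that("perfect predictions give unit precision and recall", {
  truths <- dplyr::mutate(random_boxes(5),
                          label = c("NET", "PMN", "PMN", "PER", "RUP"))
  rep <- evaluate_annotations(truths, truths)
  expect_true(all(rep$stats$precision == 1))
  expect_true(all(rep$stats$recall == 1))
  expect_equal(rep$summary$avg_precision, 1)
  g <- glance(rep)
  expect_equal(g$n_matched, 5)
  expect_s3_class(tidy(rep), "tbl_df")
})

test_that("VOC annotations round-trip through the half-open convention", {
  boxes <- tibble::tibble(
    label = c("NET", "PMN neu"),
    rmin = c(0L, 10L), cmin = c(5L, 3L), rmax = c(7L, 22L), cmax = c(9L, 11L)
  )
  path <- withr::local_tempfile(fileext = ".xml")
  write_voc_annotations(boxes, path, filename = "img.tif", dim = c(64, 64))
  back <- read_voc_annotations(path)
  expect_equal(back$label, boxes$label)
  expect_equal(back[, c("rmin", "cmin", "rmax", "cmax")],
               boxes[, c("rmin", "cmin", "rmax", "cmax")])
  # box area equals pixel count of the annotated block
  expect_equal((back$rmax - back$rmin) * (back$cmax - back$cmin),
               c(7L * 4L, 12L * 8L))
})

test_that("match report files are written", {
  truths <- dplyr::mutate(random_boxes(4), label = c("A", "A", "B", "B"))
  rep <- evaluate_annotations(truths, truths)
  dir <- withr::local_tempdir()
  write_match_report(rep, dir)
  expect_true(all(file.exists(file.path(
    dir, c("confusion.csv", "stats.csv", "report.txt")))))
})
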