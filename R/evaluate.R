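#' Intersection over union of two bounding boxes
#'
#' Boxes use the 0-based, half-open convention `(rmin, cmin, rmax, cmax)`, so
#' the area of a box equals the number of pixels it covers.
#'
#' @param a,b Numeric length-4 vectors `(rmin, cmin, rmax, cmax)`.
#' @return IoU in `[0, 1]`; 0 for disjoint boxes.
#' @examples
#' box_iou(c(0, 0, 10, 10), c(5, 0, 15, 10))  # 50 / 150 = 1/3
#' @export
box_iou <- function(a, b) {
  if (a[3] <= a[1] || a[4] <= a[2] || b[3] <= b[1] || b[4] <= b[2]) {
    stop("structural error: degenerate bounding box", call. = FALSE)
  }
  ih <- min(a[3], b[3]) - max(a[1], b[1])
  iw <- min(a[4], b[4]) - max(a[2], b[2])
  if (ih <= 0 || iw <= 0) return(0)
  inter <- ih * iw
  area_a <- (a[3] - a[1]) * (a[4] - a[2])
  area_b <- (b[3] - b[1]) * (b[4] - b[2])
  inter / (area_a + area_b - inter)
}

box_cols <- c("rmin", "cmin", "rmax", "cmax")

#' Greedy one-to-one matching of predicted and truth boxes
#'
#' All prediction--truth pairs with IoU at or above the threshold are
#' candidates; the pair with the globally highest IoU is matched and removed,
#' repeatedly, until no candidate remains. Ties are broken deterministically
#' by (smaller prediction index, smaller truth index).
#'
#' @param preds,truths Tibbles with bounding-box columns `rmin`, `cmin`,
#'   `rmax`, `cmax` (0-based half-open).
#' @param iou_threshold Minimum IoU for a match (default 0.10).
#' @return Tibble with `pred`, `truth` (row indices) and `iou`, one row per
#'   matched pair; each box appears in at most one pair.
#' @export
match_boxes <- function(preds, truths, iou_threshold = 0.10) {
  stopifnot(iou_threshold > 0, iou_threshold <= 1)
  np <- nrow(preds); nt <- nrow(truths)
  empty <- tibble::tibble(pred = integer(), truth = integer(), iou = numeric())
  if (np == 0L || nt == 0L) return(empty)
  pb <- as.matrix(preds[, box_cols])
  tb <- as.matrix(truths[, box_cols])
  cand <- expand.grid(pred = seq_len(np), truth = seq_len(nt))
  cand$iou <- mapply(function(i, j) box_iou(pb[i, ], tb[j, ]),
                     cand$pred, cand$truth)
  cand <- cand[cand$iou >= iou_threshold, , drop = FALSE]
  cand <- cand[order(-cand$iou, cand$pred, cand$truth), , drop = FALSE]
  pairs <- list()
  used_p <- logical(np); used_t <- logical(nt)
  for (k in seq_len(nrow(cand))) {
    i <- cand$pred[k]; j <- cand$truth[k]
    if (!used_p[i] && !used_t[j]) {
      used_p[i] <- TRUE; used_t[j] <- TRUE
      pairs[[length(pairs) + 1L]] <-
        tibble::tibble(pred = i, truth = j, iou = cand$iou[k])
    }
  }
  if (length(pairs) == 0L) return(empty)
  dplyr::bind_rows(pairs)
}

#' Confusion matrix and precision/recall from matched boxes
#'
#' Builds the confusion matrix with unmatched margins: rows are predicted
#' classes plus `Unknown` plus `Unmatched`, columns are truth classes plus
#' `Unmatched`. A matched pair counts in cell (predicted label, truth label);
#' an unmatched prediction counts in the `Unmatched` column of its row; an
#' unmatched truth in the `Unmatched` row of its column. Precision and recall
#' are then computed with [confusion_stats()].
#'
#' @param pairs Output of [match_boxes()].
#' @param preds Prediction tibble with a `label` column (may include
#'   `"Unknown"`).
#' @param truths Truth tibble with a `label` column.
#' @param classes Optional ordering of the named classes; defaults to the
#'   union of labels seen (Unknown excluded).
#' @return An `nq_match_report`: list with `confusion` (matrix), `pairs`,
#'   `stats` (per-class tibble) and `summary` (one-row tibble of averages).
#' @export
confusion_and_stats <- function(pairs, preds, truths, classes = NULL) {
  pred_lab <- normalize_unknown(preds$label)
  truth_lab <- truths$label
  if (is.null(classes)) {
    classes <- sort(unique(c(setdiff(pred_lab, "Unknown"), truth_lab)))
  }
  rows <- c(classes, "Unknown", "Unmatched")
  cols <- c(classes, "Unmatched")
  conf <- matrix(0L, length(rows), length(cols),
                 dimnames = list(predicted = rows, truth = cols))
  matched_p <- logical(nrow(preds)); matched_t <- logical(nrow(truths))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$pred[k]; j <- pairs$truth[k]
    matched_p[i] <- TRUE; matched_t[j] <- TRUE
    conf[pred_lab[i], truth_lab[j]] <- conf[pred_lab[i], truth_lab[j]] + 1L
  }
  for (i in which(!matched_p)) {
    conf[pred_lab[i], "Unmatched"] <- conf[pred_lab[i], "Unmatched"] + 1L
  }
  for (j in which(!matched_t)) {
    conf["Unmatched", truth_lab[j]] <- conf["Unmatched", truth_lab[j]] + 1L
  }
  stats <- confusion_stats(conf, classes = classes)
  structure(list(confusion = conf, pairs = pairs,
                 stats = stats$stats, summary = stats$summary),
            class = "nq_match_report")
}

normalize_unknown <- function(labels) {
  ifelse(labels %in% c("UNKNOWN_INTRACELLULAR", "UNKNOWN_EXTRACELLULAR",
                       "EXTRA_ARTIFACT", "Unknown", "unknown"),
         "Unknown", labels)
}

#' Precision and recall from a confusion matrix with unmatched margins
#'
#' For each named class `c`: `precision(c)` is the diagonal cell divided by
#' the total of the class's prediction row (including its `Unmatched` cell);
#' `recall(c)` is the diagonal cell divided by the total of the class's truth
#' column (including its `Unknown` and `Unmatched` cells). The `Unknown` and
#' `Unmatched` rows get no precision; the `Unmatched` column gets no recall.
#' Averages are unweighted means over the named classes.
#'
#' @param conf Integer matrix whose rownames are predicted classes (optionally
#'   plus `Unknown` and `Unmatched`) and colnames truth classes (optionally
#'   plus `Unmatched`).
#' @param classes Named classes to report; default: rownames also present in
#'   colnames.
#' @return List with `stats` (tibble: class, precision, recall, predicted
#'   total, truth total) and `summary` (tibble: avg_precision, avg_recall).
#' @examples
#' conf <- matrix(c(9, 1, 0, 10), 2, 2,
#'                dimnames = list(c("A", "B"), c("A", "B")))
#' confusion_stats(conf)$stats
#' @export
confusion_stats <- function(conf, classes = NULL) {
  if (is.null(classes)) {
    classes <- intersect(rownames(conf), colnames(conf))
    classes <- setdiff(classes, c("Unknown", "Unmatched"))
  }
  stats <- purrr::map_dfr(classes, function(cl) {
    row_total <- sum(conf[cl, ])
    col_total <- sum(conf[, cl])
    tibble::tibble(
      class = cl,
      n_predicted = row_total,
      n_truth = col_total,
      precision = if (row_total > 0) conf[cl, cl] / row_total else NA_real_,
      recall = if (col_total > 0) conf[cl, cl] / col_total else NA_real_
    )
  })
  list(stats = stats,
       summary = tibble::tibble(
         avg_precision = mean(stats$precision, na.rm = TRUE),
         avg_recall = mean(stats$recall, na.rm = TRUE)))
}

#' Evaluate predictions against ground-truth annotations
#'
#' One-stop wrapper: greedy IoU matching followed by the confusion matrix and
#' precision/recall statistics. Predictions can come from a processed image
#' (`tidy(nq_result)`), a per-ROI CSV, or any tibble with bounding boxes and
#' labels.
#'
#' @param preds,truths Tibbles with `rmin`, `cmin`, `rmax`, `cmax`, `label`.
#'   When both carry a `source_id` column, matching is performed within each
#'   image and the confusion matrix pools all images.
#' @param iou_threshold Minimum IoU for a match (default 0.10).
#' @param classes Optional class ordering.
#' @return An `nq_match_report`.
#' @export
evaluate_annotations <- function(preds, truths, iou_threshold = 0.10,
                                 classes = NULL) {
  grouped <- "source_id" %in% names(preds) && "source_id" %in% names(truths)
  pairs <- if (!grouped) {
    match_boxes(preds, truths, iou_threshold)
  } else {
    ids <- union(preds$source_id, truths$source_id)
    purrr::map_dfr(ids, function(id) {
      ip <- which(preds$source_id == id)
      it <- which(truths$source_id == id)
      m <- match_boxes(preds[ip, ], truths[it, ], iou_threshold)
      dplyr::mutate(m, pred = ip[.data$pred], truth = it[.data$truth])
    })
  }
  confusion_and_stats(pairs, preds, truths, classes = classes)
}

#' @export
print.nq_match_report <- function(x, ...) {
  cat("<nq_match_report>\n")
  print(x$confusion)
  st <- x$stats
  for (i in seq_len(nrow(st))) {
    cat(sprintf("  %-10s precision %.2f  recall %.2f\n", st$class[i],
                st$precision[i], st$recall[i]))
  }
  cat(sprintf("  average    precision %.2f  recall %.2f\n",
              x$summary$avg_precision, x$summary$avg_recall))
  invisible(x)
}

#' @rdname evaluate_annotations
#' @param x An `nq_match_report`.
#' @param ... Unused.
#' @export
tidy.nq_match_report <- function(x, ...) {
  x$stats
}

#' @rdname evaluate_annotations
#' @export
glance.nq_match_report <- function(x, ...) {
  dplyr::mutate(x$summary,
                n_matched = nrow(x$pairs),
                n_predictions = sum(x$confusion[setdiff(
                  rownames(x$confusion), "Unmatched"), ]),
                n_truths = sum(x$confusion[, setdiff(
                  colnames(x$confusion), "Unmatched")]))
}

#' Write a match report to disk
#'
#' Writes the confusion matrix and the per-class statistics as CSV plus a
#' formatted text table (two-decimal precision/recall, as in human-readable
#' reports; the CSV keeps full precision).
#'
#' @param report An `nq_match_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_match_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  conf_df <- tibble::as_tibble(report$confusion, rownames = "predicted")
  readr::write_csv(conf_df, file.path(dir, "confusion.csv"))
  readr::write_csv(report$stats, file.path(dir, "stats.csv"))
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
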