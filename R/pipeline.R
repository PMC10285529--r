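#' Stage 1: classify extracellular-channel ROIs
#'
#' Small extracellular ROIs (area below `min_net_area`) typically correspond
#' to neutrophils with a permeabilized plasma membrane and are skipped here
#' (they are recovered at stage 2 through the `mean_extra` feature of the
#' matching total-DNA ROI). A remaining ROI is a NET when its mean and
#' standard deviation of extracellular brightness fall inside the configured
#' ranges; anything else is flagged `EXTRA_ARTIFACT` ("extracellular
#' unknown": uneven background, autofluorescence, or atypical NETs needing
#' manual inspection). In `mode = "soft"` the two interval tests are replaced
#' by the product of [partial_score()]s compared against `assign_threshold`.
#'
#' @param features Feature tibble of extracellular-channel ROIs.
#' @param stage1 Stage-1 parameter list (see [netquant_config()]).
#' @param s,assign_threshold Used only in soft mode.
#' @return `features` with a `label` column
#'   (`NET` / `EXTRA_ARTIFACT` / `SKIPPED_SMALL`).
#' @export
stage1_classify_extracellular <- function(features, stage1, s = 0.5,
                                          assign_threshold = 0.8) {
  mode <- stage1$mode %||% "hard"
  mr <- stage1$net_mean_range
  sr <- stage1$net_std_range
  lab <- character(nrow(features))
  for (i in seq_len(nrow(features))) {
    if (features$area[i] < stage1$min_net_area) {
      lab[i] <- "SKIPPED_SMALL"
    } else if (mode == "hard") {
      is_net <- features$mean_extra[i] >= mr[1] &&
        features$mean_extra[i] <= mr[2] &&
        features$std_extra[i] >= sr[1] && features$std_extra[i] <= sr[2]
      lab[i] <- if (is_net) "NET" else "EXTRA_ARTIFACT"
    } else {
      sc <- partial_score(features$mean_extra[i], mr[1], mr[2], s) *
        partial_score(features$std_extra[i], sr[1], sr[2], s)
      lab[i] <- if (sc >= assign_threshold) "NET" else "EXTRA_ARTIFACT"
    }
  }
  dplyr::mutate(features, label = lab)
}

#' Binary mask of NET and artifact regions
#'
#' The union of the pixel sets of all stage-1 `NET` and `EXTRA_ARTIFACT`
#' ROIs; `SKIPPED_SMALL` ROIs contribute nothing.
#'
#' @param stage1_out Output of [stage1_classify_extracellular()].
#' @param dim Image dimensions `c(nrow, ncol)`.
#' @return Logical matrix.
#' @export
build_mask <- function(stage1_out, dim) {
  mask <- matrix(FALSE, dim[1], dim[2])
  keep <- which(stage1_out$label %in% c("NET", "EXTRA_ARTIFACT"))
  for (i in keep) {
    px <- stage1_out$pixels[[i]]
    mask[cbind(px[, 1], px[, 2])] <- TRUE
  }
  mask
}

#' Stage 2: classify total-DNA-channel ROIs
#'
#' ROIs lying (more than `mask_overlap` of their pixels) inside the
#' NET/artifact mask are marked `IGNORED_MASKED` and excluded from counting:
#' within such regions it cannot be decided reliably whether a cell's
#' membrane is permeabilized. All other ROIs are scored against the
#' intracellular class definitions and labelled by the
#' unambiguous-assignment rule; unassigned ROIs become
#' `UNKNOWN_INTRACELLULAR`.
#'
#' @param features Feature tibble of total-DNA-channel ROIs.
#' @param mask Logical matrix from [build_mask()].
#' @param config A [netquant_config()].
#' @param candidates Optional subset of class names (default: all configured).
#' @return `features` with score columns, `label`, `score`,
#'   `ambiguity_reason` and `mask_fraction`.
#' @export
stage2_classify_intracellular <- function(features, mask, config,
                                          candidates = NULL) {
  frac <- purrr::map_dbl(features$pixels, function(px) {
    mean(mask[cbind(px[, 1], px[, 2])])
  })
  if (nrow(features) == 0L) frac <- numeric(0)
  classes <- config_classes(config, candidates)
  out <- classify_features(features, classes, s = config$s,
                           assign_threshold = config$assign_threshold,
                           reject_threshold = config$reject_threshold,
                           unknown_label = "UNKNOWN_INTRACELLULAR")
  out$mask_fraction <- frac
  masked <- frac > config$mask_overlap
  out$label[masked] <- "IGNORED_MASKED"
  out$ambiguity_reason[masked] <- "none"
  out
}

#' Per-image annotation quality score
#'
#' `Q = 100 * (1 - U / S)` percent, where `U` is the pixel area covered by
#' unclassified ROIs and `S` the area covered by all retained ROIs on both
#' channels. Areas rather than counts make the score robust to small
#' artifacts. `IGNORED_MASKED` and `SKIPPED_SMALL` ROIs enter neither `U` nor
#' `S`; extracellular artifacts count as unclassified by default (they
#' require manual inspection) but can be excluded via
#' `include_artifacts = FALSE`. An image with no retained ROIs scores 100.
#'
#' @param labels Character vector of per-ROI labels (both channels).
#' @param areas Integer vector of per-ROI pixel areas.
#' @param include_artifacts Count `EXTRA_ARTIFACT` area as unclassified.
#' @return List with `Q`, `U` and `S_total`.
#' @export
quality_score <- function(labels, areas, include_artifacts = TRUE) {
  stopifnot(length(labels) == length(areas))
  retained <- !labels %in% c("IGNORED_MASKED", "SKIPPED_SMALL")
  unknown_labels <- "UNKNOWN_INTRACELLULAR"
  if (include_artifacts) unknown_labels <- c(unknown_labels, "EXTRA_ARTIFACT")
  S_total <- sum(areas[retained])
  U <- sum(areas[retained & labels %in% unknown_labels])
  Q <- if (S_total == 0) 100 else 100 * (1 - U / S_total)
  list(Q = Q, U = U, S_total = S_total)
}

#' Process one two-channel image through the full workflow
#'
#' Runs the complete chain: optional per-channel filtering, threshold
#' segmentation of both channels, feature extraction, stage-1 extracellular
#' classification, NET/artifact masking, stage-2 intracellular
#' classification, and the per-image summary with quality score. The result
#' is deterministic for fixed input and configuration.
#'
#' @param total,extra The two channels (`channel_image` or matrix), or
#'   `total` may be the list returned by [read_two_channel_tiff()], or a
#'   path to a two-channel TIFF.
#' @param config A [netquant_config()] with class definitions.
#' @param candidates Optional intracellular candidate class subset.
#' @return An object of class `nq_result`: list with `rois` (per-ROI tibble,
#'   both channels, with features, scores and labels), `summary` (one-row
#'   tibble), `label_maps` (per channel) and `source_id`. Use [tidy()] /
#'   [glance()] / [ggplot2::autoplot()] on it.
#' @export
process_image <- function(total, extra = NULL, config, candidates = NULL) {
  if (is.character(total)) {
    total <- read_two_channel_tiff(total)
  }
  if (is.list(total) && !inherits(total, "channel_image") &&
      all(c("total_dna", "extracellular_dna") %in% names(total))) {
    extra <- total$extracellular_dna
    total <- total$total_dna
  }
  if (is.null(extra)) {
    stop("input error: extracellular channel missing", call. = FALSE)
  }
  total <- as_channel_image(total, "total_dna")
  extra <- as_channel_image(extra, "extracellular_dna",
                            source_id = total$source_id)
  if (!identical(dim(total$pixels), dim(extra$pixels))) {
    stop(sprintf("input error: channel dimensions differ in %s",
                 total$source_id), call. = FALSE)
  }

  seg <- config$segmentation
  chans <- list(total_dna = total, extracellular_dna = extra)
  for (ch in names(chans)) {
    p <- seg[[ch]]
    chans[[ch]] <- apply_filter(chans[[ch]], p$filter %||% "none",
                                sigma = p$sigma %||% 2,
                                radius = p$radius %||% 1)
  }

  rois <- lapply(names(chans), function(ch) {
    p <- seg[[ch]]
    threshold_segment(chans[[ch]], threshold = p$threshold,
                      min_area = p$min_area, connectivity = p$connectivity)
  })
  names(rois) <- names(chans)

  feats <- lapply(rois, compute_features,
                  total_img = chans$total_dna,
                  extra_img = chans$extracellular_dna,
                  log_sigma = config$log_sigma)

  stage1 <- stage1_classify_extracellular(
    feats$extracellular_dna, config$stage1,
    s = config$s, assign_threshold = config$assign_threshold)
  mask <- build_mask(stage1, dim(total$pixels))
  stage2 <- stage2_classify_intracellular(
    feats$total_dna, mask, config, candidates = candidates)

  all_rois <- dplyr::bind_rows(
    dplyr::mutate(stage2, channel = "total_dna"),
    dplyr::mutate(stage1, channel = "extracellular_dna")
  )
  q <- quality_score(all_rois$label, all_rois$area,
                     include_artifacts = config$quality_includes_artifacts)

  net_px <- sum(all_rois$area[all_rois$label == "NET"])
  named <- c("PMN", "RND", "RUP", "PER", "BACTERIA", "NET", "EXTRA_ARTIFACT",
             "UNKNOWN_INTRACELLULAR", "IGNORED_MASKED", "SKIPPED_SMALL")
  counts <- as.list(setNames(
    vapply(named, function(cl) sum(all_rois$label == cl), 0L), named))
  summary <- tibble::as_tibble(c(
    list(source_id = total$source_id),
    counts,
    list(n_rois = nrow(all_rois),
         net_area_fraction = 100 * net_px / length(total$pixels),
         U = q$U, S_total = q$S_total, quality_score = q$Q)
  ))

  structure(list(
    rois = all_rois,
    summary = summary,
    label_maps = lapply(rois, as_label_map, dim = dim(total$pixels)),
    source_id = total$source_id,
    dim = dim(total$pixels)
  ), class = "nq_result")
}

#' @export
print.nq_result <- function(x, ...) {
  cat(sprintf("<nq_result> %s: %d ROIs, Q = %.1f%%\n",
              x$source_id, nrow(x$rois), x$summary$quality_score))
  cnt <- x$summary
  cls <- c("PMN", "RND", "RUP", "PER", "BACTERIA", "NET", "EXTRA_ARTIFACT",
           "UNKNOWN_INTRACELLULAR", "IGNORED_MASKED", "SKIPPED_SMALL")
  shown <- cls[unlist(cnt[cls]) > 0]
  if (length(shown)) {
    cat(paste(sprintf("  %s: %d", shown, unlist(cnt[shown])), collapse = "\n"),
        "\n")
  }
  invisible(x)
}

#' @rdname process_image
#' @param x An `nq_result`.
#' @param ... Unused.
#' @export
tidy.nq_result <- function(x, ...) {
  dplyr::select(x$rois, -"pixels")
}

#' @rdname process_image
#' @export
glance.nq_result <- function(x, ...) {
  x$summary
}

#' Predicted objects of a processed image, ready for evaluation
#'
#' Returns the labelled ROIs of an `nq_result` as a box table suitable for
#' [evaluate_annotations()]: `SKIPPED_SMALL` extracellular components (the
#' footprints of PER cells, already represented by their total-DNA ROI) and
#' `IGNORED_MASKED` ROIs are dropped.
#'
#' @param x An `nq_result`.
#' @return Tibble with `roi_id`, `channel`, `label`, `score` (where
#'   applicable) and bounding-box columns.
#' @export
result_predictions <- function(x) {
  stopifnot(inherits(x, "nq_result"))
  keep <- !x$rois$label %in% c("SKIPPED_SMALL", "IGNORED_MASKED")
  dplyr::select(x$rois[keep, ],
                dplyr::any_of(c("roi_id", "channel", "label", "score",
                                "rmin", "cmin", "rmax", "cmax")))
}

#' Process a batch of images
#'
#' Applies [process_image()] to each input and binds one summary row per
#' image in input order. Images that fail to load or process are reported
#' (warning + a `skipped` attribute on the result) and skipped, never fatal.
#'
#' @param inputs Character vector of two-channel TIFF paths, or a list whose
#'   elements are acceptable `total` arguments to [process_image()].
#' @param config A [netquant_config()].
#' @param out Optional path for the summary CSV. A `.xlsx` extension is not
#'   supported; a CSV (readable by spreadsheet software) is written instead
#'   with a warning.
#' @param per_roi Optional path for a combined per-ROI CSV.
#' @param labelmaps_dir Optional directory for per-channel label-map TIFFs.
#' @param candidates Optional intracellular candidate class subset.
#' @param quiet Suppress the per-image progress line.
#' @param q_alert Emit a warning for images with quality score below this
#'   level (default `NA`, off).
#' @return Tibble of per-image summaries (attribute `skipped`: tibble of
#'   failed inputs and error messages).
#' @export
process_batch <- function(inputs, config, out = NULL, per_roi = NULL,
                          labelmaps_dir = NULL, candidates = NULL,
                          quiet = TRUE, q_alert = NA) {
  if (length(inputs) == 0L) {
    stop("usage error: empty input list", call. = FALSE)
  }
  summaries <- list()
  roi_tables <- list()
  skipped <- list()
  for (i in seq_along(inputs)) {
    input <- if (is.list(inputs)) inputs[[i]] else inputs[i]
    id <- if (is.character(input)) basename(input) else sprintf("image_%03d", i)
    res <- tryCatch(
      process_image(input, config = config, candidates = candidates),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      warning(sprintf("skipping %s: %s", id, conditionMessage(res)),
              call. = FALSE)
      skipped[[length(skipped) + 1L]] <-
        tibble::tibble(source_id = id, error = conditionMessage(res))
      next
    }
    if (res$source_id == "image") res$summary$source_id <- id
    summaries[[length(summaries) + 1L]] <- res$summary
    if (!is.null(per_roi)) {
      roi_tables[[length(roi_tables) + 1L]] <- dplyr::mutate(
        dplyr::select(res$rois, -"pixels"),
        source_id = res$summary$source_id, .before = 1)
    }
    if (!is.null(labelmaps_dir)) {
      for (ch in names(res$label_maps)) {
        write_label_map(res$label_maps[[ch]], file.path(
          labelmaps_dir, sprintf("%s_%s_labels.tif",
                                 sub("\\.[^.]+$", "", res$summary$source_id),
                                 ch)))
      }
    }
    if (!quiet) {
      message(sprintf("%s: %d ROIs, Q = %.1f%%", res$summary$source_id,
                      res$summary$n_rois, res$summary$quality_score))
    }
    if (!is.na(q_alert) && res$summary$quality_score < q_alert) {
      warning(sprintf("%s: quality score %.1f%% below alert level %.1f%%",
                      res$summary$source_id, res$summary$quality_score,
                      q_alert), call. = FALSE)
    }
  }
  report <- dplyr::bind_rows(summaries)
  if (!is.null(out)) {
    if (grepl("\\.xlsx?$", out, ignore.case = TRUE)) {
      out_csv <- sub("\\.xlsx?$", ".csv", out, ignore.case = TRUE)
      warning(sprintf(
        "xlsx output is not supported; writing CSV to %s instead", out_csv),
        call. = FALSE)
      out <- out_csv
    }
    readr::write_csv(report, out)
  }
  if (!is.null(per_roi)) {
    readr::write_csv(dplyr::bind_rows(roi_tables), per_roi)
  }
  attr(report, "skipped") <- dplyr::bind_rows(skipped)
  report
}
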