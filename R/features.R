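#' Compute per-ROI classification features
#'
#' For each segmented ROI the classifier uses: `area` (pixel count),
#' `mean_total` (mean intensity over the ROI's own pixels in the total-DNA
#' channel), `mean_extra` and `std_extra` (mean and population standard
#' deviation in the extracellular-DNA channel), and `mean_log` (mean
#' Laplacian-of-Gaussian response in the total-DNA channel; bright compact
#' blobs give a negative value, diffuse edge-less clumps a value near zero).
#' Two circularity ratios (`circ_perimeter = area / perimeter^2`,
#' `circ_diameter = area / diameter^2`) are computed as optional descriptive
#' features; they are not used by any default class definition. All features
#' are evaluated over the ROI's pixel set, never its bounding box; ROIs
#' segmented on either channel use the same definitions, with total-channel
#' features read under the ROI footprint.
#'
#' @param rois ROI tibble from [threshold_segment()].
#' @param total_img,extra_img The two `channel_image`s (same dimensions).
#' @param log_sigma Gaussian scale of the LoG kernel in pixels (default 2).
#' @param circularity Compute the circularity ratios (default `TRUE`).
#' @return The input tibble with feature columns appended.
#' @export
compute_features <- function(rois, total_img, extra_img, log_sigma = 2,
                             circularity = TRUE) {
  total <- if (inherits(total_img, "channel_image")) total_img$pixels else total_img
  extra <- if (inherits(extra_img, "channel_image")) extra_img$pixels else extra_img
  if (!identical(dim(total), dim(extra))) {
    stop("structural error: channel dimensions differ", call. = FALSE)
  }
  if (nrow(rois) == 0L) {
    return(dplyr::mutate(rois,
      mean_total = numeric(0), mean_extra = numeric(0),
      std_extra = numeric(0), mean_log = numeric(0),
      circ_perimeter = numeric(0), circ_diameter = numeric(0)))
  }
  nr <- nrow(total); nc <- ncol(total)
  bad <- purrr::map_lgl(rois$pixels, function(px) {
    any(px[, 1] < 1L | px[, 1] > nr | px[, 2] < 1L | px[, 2] > nc)
  })
  if (any(bad)) {
    stop("structural error: ROI pixels outside image bounds", call. = FALSE)
  }

  log_img <- log_response(total, sigma = log_sigma)
  feats <- purrr::map_dfr(rois$pixels, function(px) {
    tv <- total[px]; ev <- extra[px]
    tibble::tibble(
      mean_total = mean(tv),
      mean_extra = mean(ev),
      std_extra = pop_sd(ev),
      mean_log = mean(log_img[px])
    )
  })
  out <- dplyr::bind_cols(rois, feats)
  if (circularity) {
    circ <- purrr::map_dfr(rois$pixels, compute_circularity)
    out <- dplyr::bind_cols(out, circ)
  }
  out
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Laplacian-of-Gaussian response of a raster
#'
#' Convolution with the analytic LoG kernel (the Laplacian of a Gaussian of
#' scale `sigma`), with the discretized kernel recentred to sum exactly to
#' zero so constant and affine-ramp images give a zero response away from the
#' border. Borders are handled by replication.
#'
#' @param pixels Numeric matrix.
#' @param sigma Gaussian scale in pixels (`> 0`).
#' @return Numeric matrix of the same dimensions (units: intensity / px^2).
#' @export
log_response <- function(pixels, sigma = 2) {
  stopifnot(sigma > 0)
  convolve_replicate(pixels, log_kernel(sigma, dim(pixels)))
}

log_kernel <- function(sigma, img_dim) {
  half <- max(1L, min(ceiling(4 * sigma), (min(img_dim) - 1L) %/% 2L))
  x <- seq(-half, half)
  g <- expand.grid(r = x, c = x)
  r2 <- g$r^2 + g$c^2
  k <- (r2 - 2 * sigma^2) / (sigma^4) * exp(-r2 / (2 * sigma^2)) /
    (2 * pi * sigma^2)
  k <- matrix(k, length(x), length(x))
  k - mean(k)
}

#' Circularity ratios of one ROI
#'
#' `circ_perimeter` is `area / perimeter^2` with the perimeter counted as the
#' number of pixel edges bordering background (set `method = "contour"` for a
#' smoothed contour-length estimate). `circ_diameter` is `area / diameter^2`
#' with the diameter the maximal pairwise distance between pixel centres; for
#' a single pixel the diameter is 0 and `circ_diameter` is returned as `NA`
#' (undefined).
#'
#' @param px Two-column (row, col) matrix of pixel coordinates.
#' @param method Perimeter estimator: `"edges"` (default) or `"contour"`.
#' @return One-row tibble with `circ_perimeter` and `circ_diameter`.
#' @export
compute_circularity <- function(px, method = c("edges", "contour")) {
  method <- match.arg(method)
  n <- nrow(px)
  stopifnot(n >= 1L)
  keys <- paste(px[, 1], px[, 2])
  perim <- if (method == "edges") {
    inside <- 0L
    for (off in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      nb <- paste(px[, 1] + off[1], px[, 2] + off[2])
      inside <- inside + sum(nb %in% keys)
    }
    4L * n - inside
  } else {
    contour_perimeter(px)
  }
  d <- max_pair_distance(px)
  tibble::tibble(
    circ_perimeter = if (perim > 0) n / perim^2 else NA_real_,
    circ_diameter = if (d > 0) n / d^2 else NA_real_
  )
}

# Smoothed contour-length estimate via EBImage's shape features on a minimal
# crop of the ROI.
contour_perimeter <- function(px) {
  r0 <- min(px[, 1]) - 1L; c0 <- min(px[, 2]) - 1L
  m <- matrix(0L, max(px[, 1]) - r0 + 2L, max(px[, 2]) - c0 + 2L)
  m[cbind(px[, 1] - r0, px[, 2] - c0)] <- 1L
  as.numeric(EBImage::computeFeatures.shape(m)[1, "s.perimeter"])
}

max_pair_distance <- function(px) {
  if (nrow(px) == 1L) return(0)
  pts <- unique(px)
  if (nrow(pts) > 3L) {
    hull <- grDevices::chull(pts[, 2], pts[, 1])
    pts <- pts[hull, , drop = FALSE]
  }
  max(stats::dist(pts))
}

#' Export a per-ROI feature table to CSV
#'
#' Writes `source_id`, `channel`, `roi_id`, the feature columns and the
#' bounding box (0-based half-open) for downstream use.
#'
#' @param features Feature tibble from [compute_features()].
#' @param path Output CSV path.
#' @param source_id Image identifier recorded in the table.
#' @return The exported tibble, invisibly.
#' @export
write_feature_table <- function(features, path, source_id = "image") {
  cols <- intersect(
    c("roi_id", "channel", "area", "mean_total", "mean_extra", "std_extra",
      "mean_log", "circ_perimeter", "circ_diameter",
      "rmin", "cmin", "rmax", "cmax", "label", "score", "ambiguity_reason"),
    names(features)
  )
  out <- dplyr::bind_cols(tibble::tibble(source_id = rep(source_id,
                                                         nrow(features))),
                          features[, cols])
  readr::write_csv(out, path)
  invisible(out)
}
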