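#' Segment a channel into ROIs by thresholding and connected components
#'
#' Pixels with intensity strictly greater than `threshold` are foreground;
#' maximal connected components under the chosen neighbourhood become ROIs.
#' Components smaller than `min_area` pixels are discarded. Bounding boxes use
#' the 0-based, half-open convention `(rmin, cmin, rmax, cmax)` so that box
#' area equals pixel extent for rectangular ROIs.
#'
#' @param img A `channel_image` or numeric matrix.
#' @param threshold Intensity threshold (native units, `>= 0`); strictly
#'   greater-than comparison, so `threshold = 0` excludes an exactly-zero
#'   background.
#' @param min_area Minimum component area in pixels (default 4, suppressing
#'   single-pixel noise).
#' @param connectivity 8 (default; diagonal neighbours connect) or 4.
#' @return A tibble with one row per ROI: `roi_id`, `channel`, `area`,
#'   bounding box columns `rmin`, `cmin`, `rmax`, `cmax`, and a `pixels`
#'   list-column of two-column (row, col) matrices in 1-based matrix indices.
#'   ROI ids follow column-major first-pixel order and are dense `1..n`.
#' @examples
#' m <- matrix(0, 10, 10); m[2:6, 2:6] <- 100
#' threshold_segment(m, threshold = 50, min_area = 1)
#' @export
threshold_segment <- function(img, threshold, min_area = 4L,
                              connectivity = 8L) {
  pixels <- if (inherits(img, "channel_image")) img$pixels else img
  role <- if (inherits(img, "channel_image")) img$channel_role else NA_character_
  if (!is.matrix(pixels) || length(pixels) == 0L) {
    stop("structural error: empty or non-matrix image", call. = FALSE)
  }
  stopifnot(threshold >= 0, min_area >= 1, connectivity %in% c(4L, 8L))

  mask <- pixels > threshold
  lab <- label_components(mask, connectivity)
  rois_from_labels(lab, min_area = min_area, channel = role)
}

#' Label connected components of a binary mask
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix; background 0, components numbered in column-major
#'   first-pixel order.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask), is.matrix(mask), connectivity %in% c(4L, 8L))
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(lab)

  fg <- integer(nr * nc)
  fg[idx] <- seq_along(idx)

  offsets <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) {
    offsets <- c(offsets, list(c(1L, 1L), c(-1L, 1L)))
  }
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  e_from <- integer(0); e_to <- integer(0)
  for (off in offsets) {
    r2 <- rows + off[1]; c2 <- cols + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- fg[nb] > 0L
    e_from <- c(e_from, fg[idx[ok]][hit])
    e_to <- c(e_to, fg[nb][hit])
  }
  g <- igraph::make_graph(rbind(e_from, e_to), n = length(idx),
                          directed = FALSE)
  memb <- igraph::components(g)$membership
  # relabel deterministically by first occurrence in column-major order
  relab <- match(memb, unique(memb))
  lab[idx] <- relab
  lab
}

#' Convert a label map into an ROI tibble
#'
#' @param lab Integer label matrix (0 = background).
#' @param min_area Discard components smaller than this.
#' @param channel Channel role to record (or `NA`).
#' @return ROI tibble as in [threshold_segment()].
#' @export
rois_from_labels <- function(lab, min_area = 1L, channel = NA_character_) {
  nr <- nrow(lab)
  idx <- which(lab > 0L)
  empty <- tibble::tibble(
    roi_id = integer(), channel = character(), area = integer(),
    rmin = integer(), cmin = integer(), rmax = integer(), cmax = integer(),
    pixels = list()
  )
  if (length(idx) == 0L) return(empty)

  groups <- split(idx, lab[idx])
  groups <- groups[order(as.integer(names(groups)))]
  groups <- groups[lengths(groups) >= min_area]
  if (length(groups) == 0L) return(empty)

  purrr::imap_dfr(unname(groups), function(ids, k) {
    r <- ((ids - 1L) %% nr) + 1L
    c_ <- ((ids - 1L) %/% nr) + 1L
    tibble::tibble(
      roi_id = k, channel = channel, area = length(ids),
      rmin = min(r) - 1L, cmin = min(c_) - 1L,
      rmax = max(r), cmax = max(c_),
      pixels = list(cbind(row = r, col = c_))
    )
  })
}
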