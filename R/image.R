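#' Construct a channel image
#'
#' A `channel_image` wraps one 2D raster of non-negative fluorescence
#' intensities (native camera units) together with its channel role:
#' `"total_dna"` for a cell-permeable stain (e.g. Hoechst 33342) imaging all
#' DNA, or `"extracellular_dna"` for a cell-impermeable stain (e.g. SYTOX
#' Green) imaging DNA accessible from outside intact membranes.
#'
#' @param pixels Numeric matrix of intensities, all `>= 0`.
#' @param channel_role `"total_dna"` or `"extracellular_dna"`.
#' @param source_id Identifier of the source image (file name or label).
#' @return An object of class `channel_image`.
#' @examples
#' img <- channel_image(matrix(0, 8, 8), "total_dna", "blank")
#' dim(img$pixels)
#' @export
channel_image <- function(pixels,
                          channel_role = c("total_dna", "extracellular_dna"),
                          source_id = "image") {
  channel_role <- match.arg(channel_role)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have positive width and height", call. = FALSE)
  }
  if (anyNA(pixels) || any(pixels < 0)) {
    stop("intensities must be non-negative and non-missing", call. = FALSE)
  }
  structure(
    list(pixels = pixels, channel_role = channel_role,
         source_id = as.character(source_id)),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s  %d x %d  role=%s  range=[%g, %g]\n",
              x$source_id, nrow(x$pixels), ncol(x$pixels), x$channel_role,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

as_channel_image <- function(x, channel_role, source_id = "image") {
  if (inherits(x, "channel_image")) return(x)
  channel_image(x, channel_role, source_id)
}

#' Read a two-channel fluorescence image from TIFF
#'
#' Reads either a single multi-page/multi-channel TIFF or two single-channel
#' TIFF files, returning one `channel_image` per role. Pixel values are
#' returned in native units (raw integer sample values; a 16-bit image keeps
#' its 0--65535 scale).
#'
#' @param path Path to a multi-page TIFF, or a character vector of two paths.
#' @param roles Channel-to-role mapping: for a multi-page file, a character
#'   vector naming the role of each page in order; for two files, the role of
#'   each file. Defaults to `c("total_dna", "extracellular_dna")`.
#' @param source_id Identifier to attach; defaults to the file name.
#' @return Named list with elements `total_dna` and `extracellular_dna`.
#' @export
read_two_channel_tiff <- function(path,
                                  roles = c("total_dna", "extracellular_dna"),
                                  source_id = NULL) {
  roles <- match.arg(roles, c("total_dna", "extracellular_dna"),
                     several.ok = TRUE)
  if (!setequal(roles, c("total_dna", "extracellular_dna"))) {
    stop("`roles` must map both total_dna and extracellular_dna", call. = FALSE)
  }
  source_id <- source_id %||% basename(path[1])
  rasters <- if (length(path) == 1L) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (length(pages) < length(roles)) {
      stop(sprintf("input error: %s has %d page(s); %d channels required",
                   path, length(pages), length(roles)), call. = FALSE)
    }
    lapply(pages[seq_along(roles)], drop_to_matrix)
  } else {
    if (length(path) != length(roles)) {
      stop("input error: supply one path per channel role", call. = FALSE)
    }
    lapply(path, function(p) drop_to_matrix(tiff::readTIFF(p, as.is = TRUE)))
  }
  dims <- vapply(rasters, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(dims)) != 1L) {
    stop(sprintf("input error: channel dimensions differ in %s", source_id),
         call. = FALSE)
  }
  out <- Map(function(r, role) channel_image(r, role, source_id),
             rasters, roles)
  names(out) <- roles
  out[c("total_dna", "extracellular_dna")]
}

drop_to_matrix <- function(x) {
  # multi-sample pages come back as arrays; keep the first sample plane
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  storage.mode(x) <- "double"
  x
}

#' Write a two-channel image as a 16-bit multi-page TIFF
#'
#' Intensities are clamped to `[0, 65535]` and stored as 16-bit samples.
#'
#' @param total,extra Numeric matrices or `channel_image`s (same dimensions).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_two_channel_tiff <- function(total, extra, path) {
  mats <- lapply(list(total, extra), function(x) {
    if (inherits(x, "channel_image")) x <- x$pixels
    pmin(pmax(x, 0), 65535) / 65535
  })
  tiff::writeTIFF(mats, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Render segmented ROIs as an integer label map
#'
#' Background pixels are 0; pixels of ROI *k* (in `roi_id` order) carry the
#' value *k*.
#'
#' @param rois ROI tibble from [threshold_segment()].
#' @param dim Image dimensions `c(nrow, ncol)`.
#' @return Integer matrix.
#' @export
as_label_map <- function(rois, dim) {
  lab <- matrix(0L, dim[1], dim[2])
  if (nrow(rois) > 0) {
    for (i in seq_len(nrow(rois))) {
      px <- rois$pixels[[i]]
      lab[cbind(px[, 1], px[, 2])] <- rois$roi_id[i]
    }
  }
  lab
}

#' Write a label map as a 16-bit TIFF or PNG
#'
#' @param label_map Integer matrix (0 = background, k = ROI k).
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(label_map, path) {
  if (max(label_map) > 65535L) {
    stop("label map exceeds 16-bit range", call. = FALSE)
  }
  scaled <- label_map / 65535
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("the png package is required for PNG output", call. = FALSE)
    }
    png::writePNG(scaled, path)
  } else {
    tiff::writeTIFF(scaled, path, bits.per.sample = 16L, compression = "none")
  }
  invisible(path)
}
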