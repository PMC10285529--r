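#' Pre-processing filters
#'
#' Optional smoothing applied to a channel before segmentation. `"gaussian"`
#' convolves with an isotropic Gaussian kernel (replicated borders);
#' `"median"` replaces each pixel by the median of its `(2*radius+1)^2`
#' window, clipped at the image border so only in-image pixels enter the
#' median. `"none"` returns the input unchanged.
#'
#' @param img A `channel_image` or numeric matrix.
#' @param filter One of `"none"`, `"gaussian"`, `"median"`.
#' @param sigma Gaussian standard deviation in pixels (`> 0`).
#' @param radius Median window radius in pixels (integer `>= 1`).
#' @return An object of the same type as `img` with identical dimensions.
#' @examples
#' m <- matrix(0, 9, 9); m[5, 5] <- 100
#' apply_filter(m, "median", radius = 1)[5, 5]  # isolated pixel removed -> 0
#' @export
apply_filter <- function(img, filter = c("none", "gaussian", "median"),
                         sigma = 2, radius = 1) {
  filter <- match.arg(filter)
  pixels <- if (inherits(img, "channel_image")) img$pixels else img
  out <- switch(
    filter,
    none = pixels,
    gaussian = {
      if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
        stop("gaussian filter requires sigma > 0", call. = FALSE)
      }
      convolve_replicate(pixels, gaussian_kernel(sigma, dim(pixels)))
    },
    median = {
      if (!is.numeric(radius) || length(radius) != 1L || radius < 1 ||
          radius != round(radius)) {
        stop("median filter requires an integer radius >= 1", call. = FALSE)
      }
      median_filter(pixels, as.integer(radius))
    }
  )
  if (inherits(img, "channel_image")) {
    channel_image(pmax(out, 0), img$channel_role, img$source_id)
  } else {
    out
  }
}

# Isotropic 2D Gaussian kernel, size 2*ceil(3*sigma)+1 capped (odd) to fit the
# image so tiny rasters remain filterable.
gaussian_kernel <- function(sigma, img_dim) {
  half <- ceiling(3 * sigma)
  half <- min(half, (min(img_dim) - 1L) %/% 2L)
  half <- max(half, 0L)
  x <- seq(-half, half)
  g <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

convolve_replicate <- function(pixels, kernel) {
  if (nrow(kernel) == 1L && ncol(kernel) == 1L) return(pixels * kernel[1, 1])
  EBImage::filter2(pixels, kernel, boundary = "replicate")
}

median_filter <- function(pixels, radius) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  k <- nrow(offs)
  stack <- matrix(NA_real_, nr * nc, k)
  rows <- rep.int(seq_len(nr), nc)
  cols <- rep(seq_len(nc), each = nr)
  for (j in seq_len(k)) {
    r2 <- rows + offs$dr[j]
    c2 <- cols + offs$dc[j]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    stack[ok, j] <- pixels[cbind(r2[ok], c2[ok])]
  }
  matrix(apply(stack, 1L, stats::median, na.rm = TRUE), nr, nc)
}
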