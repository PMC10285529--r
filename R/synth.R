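#' Synthetic two-channel fluorescence scenes with ground truth
#'
#' The generator renders the morphologies seen in double-stained NETosis
#' assays so that every other module can be exercised with known ground
#' truth: PMN neutrophils as small lobulated bright-moderate objects with no
#' extracellular signal; RND neutrophils as discs with the highest total-DNA
#' brightness; RUP neutrophils as larger, dimmer cloud-like regions; PER
#' neutrophils as the only cell class carrying extracellular signal over its
#' footprint; NETs as large regions of spatially heterogeneous extracellular
#' brightness (a guaranteed standard-deviation floor); extracellular
#' artifacts as smooth near-uniform patches (the low-SD counterpart the
#' classifier must separate from NETs); and bacterial clumps as diffuse
#' low-intensity blobs with Gaussian-blurred, edge-less boundaries (small
#' mean-LoG magnitude). Intensities are on a 16-bit scale; the default
#' background level is 100 a.u. with additive Gaussian noise of SD 5 a.u.
#'
#' @param width,height Canvas dimensions in pixels (minimum 64).
#' @param objects Named integer vector of object counts per class, e.g.
#'   `c(PMN = 5, NET = 1)`. Valid names: PMN, RND, RUP, PER, NET,
#'   EXTRA_ARTIFACT, BACTERIA.
#' @param background Background intensity (a.u.), both channels.
#' @param background_gradient Amplitude (a.u.) of a diagonal linear gradient
#'   added to the extracellular channel, emulating uneven background
#'   brightness.
#' @param noise_sd Additive Gaussian noise SD (a.u.), both channels.
#' @param overlap_allowed Allow object footprints to overlap (default
#'   `FALSE`: placement retries until objects are disjoint with a safety
#'   margin, failing after bounded retries).
#' @param seed Integer seed fixing the whole scene.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(width = 256, height = 256,
                       objects = c(PMN = 5, RND = 3, RUP = 3, PER = 3,
                                   NET = 1),
                       background = 100, background_gradient = 0,
                       noise_sd = 5, overlap_allowed = FALSE, seed = 1L) {
  stopifnot(width >= 64, height >= 64, noise_sd >= 0, background >= 0)
  bad <- setdiff(names(objects), names(class_generation_specs_list()))
  if (length(bad) > 0) {
    stop("unknown object class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(width = width, height = height, objects = objects,
                 background = background,
                 background_gradient = background_gradient,
                 noise_sd = noise_sd, overlap_allowed = overlap_allowed,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Generating feature distributions per class. Intensities are sampled from
# the inner 80% of each range so that measured per-object means stay inside
# the stated range despite intra-object noise.
class_generation_specs_list <- function() {
  list(
    PMN = list(shape = "lobulated", mean_total_range = c(1500, 2400),
               mean_extra_range = c(0, 0), intra_sd = 60),
    RND = list(shape = "disc", radius_range = c(4, 6),
               mean_total_range = c(3800, 6200), mean_extra_range = c(0, 0),
               intra_sd = 80),
    RUP = list(shape = "cloud", mean_total_range = c(600, 1000),
               mean_extra_range = c(0, 0), intra_sd = 40),
    PER = list(shape = "disc", radius_range = c(4.5, 6.5),
               mean_total_range = c(1500, 2400),
               mean_extra_range = c(1000, 2800), intra_sd = 60),
    NET = list(shape = "diffuse_blob", radius_range = c(16, 24),
               mean_extra_range = c(800, 1000), extra_sd_target = 350),
    EXTRA_ARTIFACT = list(shape = "smooth_patch",
                          mean_extra_range = c(500, 900)),
    BACTERIA = list(shape = "diffuse_clump", peak_range = c(380, 550))
  )
}

#' Generating distributions of the synthetic classes
#'
#' Returns, per class, the intensity and size ranges the generator samples
#' from; useful to verify that measured features of rendered objects fall
#' where the presets promise.
#'
#' @return Tibble with one row per class.
#' @export
class_generation_specs <- function() {
  specs <- class_generation_specs_list()
  purrr::imap_dfr(specs, function(sp, nm) {
    tibble::tibble(
      class = nm, shape = sp$shape,
      mean_total_lo = (sp$mean_total_range %||% c(NA, NA))[1],
      mean_total_hi = (sp$mean_total_range %||% c(NA, NA))[2],
      mean_extra_lo = (sp$mean_extra_range %||% c(NA, NA))[1],
      mean_extra_hi = (sp$mean_extra_range %||% c(NA, NA))[2]
    )
  })
}

# sample from the inner 80% of a range
inner_sample <- function(range) {
  pad <- 0.1 * (range[2] - range[1])
  runif(1, range[1] + pad, range[2] - pad)
}

# ---- shape primitives: integer (dr, dc) offsets around the object centre ----

offsets_disc <- function(r) {
  h <- ceiling(r)
  g <- expand.grid(dr = -h:h, dc = -h:h)
  as.matrix(g[g$dr^2 + g$dc^2 <= r^2, ])
}

offsets_ellipse <- function(a, b, theta) {
  h <- ceiling(max(a, b))
  g <- expand.grid(dr = -h:h, dc = -h:h)
  x <- g$dc * cos(theta) + g$dr * sin(theta)
  y <- -g$dc * sin(theta) + g$dr * cos(theta)
  as.matrix(g[(x / a)^2 + (y / b)^2 <= 1, ])
}

offsets_union <- function(parts) {
  all <- do.call(rbind, parts)
  unique(all)
}

offsets_lobulated <- function() {
  n_lobes <- sample(2:4, 1)
  parts <- lapply(seq_len(n_lobes), function(i) {
    off <- offsets_ellipse(runif(1, 2.2, 3.6), runif(1, 2.2, 3.6),
                           runif(1, 0, pi))
    shift <- round(runif(2, -2.5, 2.5))
    cbind(dr = off[, 1] + shift[1], dc = off[, 2] + shift[2])
  })
  offsets_union(parts)
}

offsets_cloud <- function() {
  parts <- lapply(1:5, function(i) {
    off <- offsets_disc(runif(1, 4.5, 6.5))
    shift <- round(runif(2, -5, 5))
    cbind(dr = off[, 1] + shift[1], dc = off[, 2] + shift[2])
  })
  offsets_union(parts)
}

offsets_wobble_blob <- function(r) {
  h <- ceiling(r * 1.35)
  g <- expand.grid(dr = -h:h, dc = -h:h)
  rho <- sqrt(g$dr^2 + g$dc^2)
  theta <- atan2(g$dr, g$dc)
  k <- sample(3:5, 1)
  phi <- runif(1, 0, 2 * pi)
  rim <- r * (1 + 0.3 * sin(k * theta + phi))
  as.matrix(g[rho <= rim, ])
}

offsets_smooth_patch <- function() {
  offsets_ellipse(runif(1, 14, 18), runif(1, 9, 13), runif(1, 0, pi))
}

# Bacterial clump: point scatter blurred into an edge-less blob. Returns the
# offsets and the added intensity profile (truth mask = profile > 150 a.u.).
bacteria_profile <- function(peak) {
  r <- runif(1, 7, 11)
  half <- ceiling(r + 8)
  n <- 2L * half + 1L
  img <- matrix(0, n, n)
  m <- 40L
  ang <- runif(m, 0, 2 * pi)
  rad <- r * sqrt(runif(m))
  pr <- pmin(pmax(round(half + 1 + rad * sin(ang)), 1), n)
  pc <- pmin(pmax(round(half + 1 + rad * cos(ang)), 1), n)
  for (i in seq_len(m)) {
    img[pr[i], pc[i]] <- img[pr[i], pc[i]] + runif(1, 0.5, 1)
  }
  blurred <- convolve_replicate(img, gaussian_kernel(2.5, dim(img)))
  blurred <- blurred / max(blurred) * peak
  keep <- which(blurred > 150, arr.ind = TRUE)
  list(offsets = cbind(dr = keep[, 1] - (half + 1L),
                       dc = keep[, 2] - (half + 1L)),
       values = blurred[keep])
}

# smooth low-frequency field over given offsets, standardized to unit SD
smooth_field <- function(off) {
  rr <- off[, 1] - min(off[, 1]) + 1L
  cc <- off[, 2] - min(off[, 2]) + 1L
  nr <- max(rr) + 1L; nc <- max(cc) + 1L
  z <- matrix(rnorm(nr * nc), nr, nc)
  z <- convolve_replicate(z, gaussian_kernel(4, dim(z)))
  v <- z[cbind(rr, cc)]
  v <- (v - mean(v)) / max(sd(v), 1e-9)
  v <- pmin(pmax(v, -1.6), 1.6)
  (v - mean(v)) / max(sd(v), 1e-9)
}

# ---- scene rendering ----

#' Render a synthetic scene
#'
#' Deterministic for a fixed `scene_spec` (the spec's seed drives all
#' randomness; the caller's RNG state is preserved).
#'
#' @param spec A [scene_spec()].
#' @return List with `total` and `extra` (`channel_image`s) and `truth`, a
#'   tibble with one row per object: `object_id`, `label`, `area`, bounding
#'   box (`rmin`, `cmin`, `rmax`, `cmax`, 0-based half-open) and a `pixels`
#'   list-column. Attributes `counts` (named vector) and `net_area`
#'   (total NET pixels) summarize the scene.
#' @examples
#' sc <- render_scene(scene_spec(objects = c(PMN = 3), seed = 7))
#' attr(sc$truth, "counts")
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(spec$seed, render_scene_impl(spec))
}

render_scene_impl <- function(spec) {
  nr <- spec$height; nc <- spec$width
  total <- matrix(spec$background, nr, nc)
  extra <- matrix(spec$background, nr, nc)
  if (spec$background_gradient > 0) {
    grad <- outer(seq_len(nr) / nr, seq_len(nc) / nc, "+") / 2
    extra <- extra + spec$background_gradient * grad
  }
  specs <- class_generation_specs_list()
  placed_boxes <- list()
  truth <- list()
  object_id <- 0L

  counts <- spec$objects
  order_classes <- rep(names(counts), counts)
  # place large objects first so the packing succeeds at higher densities
  size_rank <- c(NET = 1, EXTRA_ARTIFACT = 2, BACTERIA = 3, RUP = 4,
                 PER = 5, RND = 6, PMN = 7)
  order_classes <- order_classes[order(size_rank[order_classes])]

  for (cl in order_classes) {
    sp <- specs[[cl]]
    obj <- switch(
      cl,
      PMN = ,
      RND = ,
      RUP = ,
      PER = {
        off <- switch(sp$shape,
                      lobulated = offsets_lobulated(),
                      disc = offsets_disc(runif(1, sp$radius_range[1],
                                                sp$radius_range[2])),
                      cloud = offsets_cloud())
        mt <- inner_sample(sp$mean_total_range)
        tv <- mt + rnorm(nrow(off), 0, sp$intra_sd)
        ev <- if (cl == "PER") {
          inner_sample(sp$mean_extra_range) + rnorm(nrow(off), 0, sp$intra_sd)
        } else {
          NULL
        }
        list(off = off, total_add = pmax(tv, 0), extra_set = ev)
      },
      NET = {
        off <- offsets_wobble_blob(runif(1, sp$radius_range[1],
                                         sp$radius_range[2]))
        mu <- inner_sample(sp$mean_extra_range)
        v <- smooth_field(off)
        list(off = off, total_add = NULL,
             extra_set = pmax(mu + sp$extra_sd_target * v, 260))
      },
      EXTRA_ARTIFACT = {
        off <- offsets_smooth_patch()
        mu <- inner_sample(sp$mean_extra_range)
        slope <- runif(1, -0.6, 0.6)
        list(off = off, total_add = NULL,
             extra_set = mu + slope * (off[, 2] - mean(off[, 2])))
      },
      BACTERIA = {
        prof <- bacteria_profile(runif(1, sp$peak_range[1], sp$peak_range[2]))
        list(off = prof$offsets, total_add = prof$values, extra_set = NULL)
      }
    )
    centre <- place_object(obj$off, nr, nc, placed_boxes,
                           overlap_allowed = spec$overlap_allowed)
    px <- cbind(row = obj$off[, 1] + centre[1], col = obj$off[, 2] + centre[2])
    if (!is.null(obj$total_add)) {
      total[px] <- spec$background + obj$total_add
    }
    if (!is.null(obj$extra_set)) {
      extra[px] <- obj$extra_set
    }
    object_id <- object_id + 1L
    placed_boxes[[length(placed_boxes) + 1L]] <-
      c(min(px[, 1]), min(px[, 2]), max(px[, 1]), max(px[, 2]))
    truth[[object_id]] <- tibble::tibble(
      object_id = object_id, label = cl, area = nrow(px),
      rmin = min(px[, 1]) - 1L, cmin = min(px[, 2]) - 1L,
      rmax = max(px[, 1]), cmax = max(px[, 2]),
      pixels = list(px)
    )
  }

  total <- total + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
  extra <- extra + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
  total <- pmin(pmax(total, 0), 65535)
  extra <- pmin(pmax(extra, 0), 65535)

  truth_tbl <- if (length(truth) > 0) dplyr::bind_rows(truth) else
    tibble::tibble(object_id = integer(), label = character(),
                   area = integer(), rmin = integer(), cmin = integer(),
                   rmax = integer(), cmax = integer(), pixels = list())
  cls <- names(class_generation_specs_list())
  attr(truth_tbl, "counts") <- setNames(
    vapply(cls, function(cl) sum(truth_tbl$label == cl), 0L), cls)
  attr(truth_tbl, "net_area") <-
    sum(truth_tbl$area[truth_tbl$label == "NET"])

  list(
    total = channel_image(total, "total_dna",
                          sprintf("synthetic_seed%d", spec$seed)),
    extra = channel_image(extra, "extracellular_dna",
                          sprintf("synthetic_seed%d", spec$seed)),
    truth = truth_tbl
  )
}

place_object <- function(off, nr, nc, placed_boxes, overlap_allowed,
                         margin = 6L, retries = 200L) {
  ext_r <- range(off[, 1]); ext_c <- range(off[, 2])
  for (i in seq_len(retries)) {
    centre <- c(
      sample(seq(1L - ext_r[1] + margin, nr - ext_r[2] - margin), 1),
      sample(seq(1L - ext_c[1] + margin, nc - ext_c[2] - margin), 1)
    )
    box <- c(centre[1] + ext_r[1] - margin, centre[2] + ext_c[1] - margin,
             centre[1] + ext_r[2] + margin, centre[2] + ext_c[2] + margin)
    if (overlap_allowed || !any(vapply(placed_boxes, function(b) {
      box[1] <= b[3] && b[1] <= box[3] && box[2] <= b[4] && b[2] <= box[4]
    }, TRUE))) {
      return(centre)
    }
  }
  stop("placement error: could not place object without overlap; ",
       "reduce object counts or enlarge the canvas", call. = FALSE)
}

# ---- fixture emission ----

fixture_presets <- function() {
  list(
    clean_separation = list(
      objects = c(PMN = 5, RND = 3, RUP = 3, PER = 3, NET = 1),
      background_gradient = 0,
      classes = c("PMN", "RND", "RUP", "PER")),
    uneven_background = list(
      objects = c(PMN = 3, PER = 2, NET = 1, EXTRA_ARTIFACT = 2),
      background_gradient = 40,
      classes = c("PMN", "RND", "RUP", "PER")),
    benchmark4class = list(
      objects = c(PMN = 4, RUP = 3, PER = 3, NET = 1),
      background_gradient = 0,
      classes = c("PMN", "RUP", "PER")),
    mixed_coculture = list(
      objects = c(PMN = 3, RND = 2, RUP = 2, PER = 2, NET = 1, BACTERIA = 2),
      background_gradient = 0,
      classes = c("PMN", "RND", "RUP", "PER", "BACTERIA"))
  )
}

#' Classifier configuration bracketing the synthetic presets
#'
#' Acceptance intervals are fixed to bracket the generating distributions of
#' [render_scene()] with a safety margin, so objects rendered by a preset are
#' recovered by the classifier. Intracellular classes are discriminated by
#' area / mean brightness / extracellular signal (plus the mean-LoG magnitude
#' for bacterial clumps); NETs and artifacts are separated at stage 1 by the
#' extracellular standard deviation.
#'
#' @param preset Preset name (see [emit_fixture_set()]).
#' @return A [netquant_config()].
#' @export
preset_config <- function(preset = "clean_separation") {
  presets <- fixture_presets()
  if (!preset %in% names(presets)) {
    stop("usage error: unknown preset '", preset, "'", call. = FALSE)
  }
  all_classes <- list(
    PMN = list(area = c(15, 170), mean_total = c(1200, 2700),
               mean_extra = c(0, 250)),
    RND = list(area = c(15, 210), mean_total = c(3400, 6600),
               mean_extra = c(0, 250)),
    RUP = list(area = c(110, 800), mean_total = c(480, 1150),
               mean_extra = c(0, 250), mean_log = c(-75, -24)),
    PER = list(area = c(25, 230), mean_total = c(1200, 2700),
               mean_extra = c(700, 3200)),
    BACTERIA = list(mean_total = c(230, 460), mean_extra = c(0, 250),
                    mean_log = c(-22, -5))
  )
  netquant_config(
    classes = all_classes[presets[[preset]]$classes],
    s = 0.2,
    segmentation = list(
      total_dna = list(threshold = 250, min_area = 4, connectivity = 8),
      extracellular_dna = list(threshold = 250, min_area = 4,
                               connectivity = 8)
    ),
    stage1 = list(min_net_area = 300, net_mean_range = c(400, 2000),
                  net_std_range = c(150, Inf), mode = "hard")
  )
}

#' Emit a set of synthetic fixture files
#'
#' Writes, for each image of a preset: a two-channel 16-bit TIFF, a
#' Pascal-VOC-style truth XML, plus (once per set) a combined truth CSV and a
#' ready-made classifier config whose acceptance intervals bracket the
#' preset's generating distributions. Presets: `"clean_separation"`
#' (well-separated cells + one NET), `"uneven_background"` (background
#' gradient and smooth extracellular artifact patches),
#' `"benchmark4class"` (PMN/RUP/PER/NET only), `"mixed_coculture"` (adds
#' bacterial clumps).
#'
#' @param preset Preset name.
#' @param out_dir Output directory (created if needed).
#' @param n_images Number of images.
#' @param seed Base seed; image *i* uses `seed + i - 1`.
#' @return Invisibly, a list with the written `images`, `annotations`,
#'   `truth_csv` and `config` paths.
#' @export
emit_fixture_set <- function(preset = "clean_separation", out_dir,
                             n_images = 10, seed = 1L) {
  presets <- fixture_presets()
  if (!preset %in% names(presets)) {
    stop("usage error: unknown preset '", preset, "'", call. = FALSE)
  }
  p <- presets[[preset]]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  images <- character(n_images)
  xmls <- character(n_images)
  truth_rows <- list()
  for (i in seq_len(n_images)) {
    sc <- render_scene(scene_spec(objects = p$objects,
                                  background_gradient = p$background_gradient,
                                  seed = seed + i - 1L))
    img_name <- sprintf("image_%03d.tif", i)
    images[i] <- file.path(out_dir, img_name)
    write_two_channel_tiff(sc$total, sc$extra, images[i])
    xmls[i] <- file.path(out_dir, sprintf("image_%03d.xml", i))
    write_voc_annotations(sc$truth, xmls[i], filename = img_name,
                          dim = dim(sc$total$pixels))
    truth_rows[[i]] <- dplyr::mutate(
      dplyr::select(sc$truth, -"pixels"),
      source_id = img_name, seed = seed + i - 1L, .before = 1)
  }
  truth_csv <- file.path(out_dir, "truth.csv")
  readr::write_csv(dplyr::bind_rows(truth_rows), truth_csv)
  config_path <- file.path(out_dir, "config.yaml")
  write_config(preset_config(preset), config_path)
  invisible(list(images = images, annotations = xmls,
                 truth_csv = truth_csv, config = config_path))
}
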