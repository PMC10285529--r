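#' Build a full analysis configuration
#'
#' Bundles all tunable parameters of the two-stage workflow. Intensities are
#' in native camera units; areas in pixels. The analysis ships no default
#' class ranges: acceptance intervals depend on staining, exposure and
#' magnification, so they must be supplied per laboratory (e.g. from a config
#' file, or the bracketing config emitted next to synthetic fixtures).
#'
#' @param classes Named list: class name -> named list of `c(l, u)` feature
#'   ranges (see [class_definition()]). NET and EXTRA_ARTIFACT are decided at
#'   stage 1 and need no entry here.
#' @param s Margin factor shared by all features (default 0.5).
#' @param assign_threshold,reject_threshold Decision thresholds (defaults 0.8
#'   and 0.4).
#' @param segmentation Per-channel segmentation parameters: a named list with
#'   entries `total_dna` and `extracellular_dna`, each a list with
#'   `threshold`, `min_area`, `connectivity`, and optional `filter`
#'   (`"none"`, `"gaussian"`, `"median"`), `sigma`, `radius`.
#' @param stage1 Extracellular-channel (stage 1) parameters: `min_net_area`,
#'   `net_mean_range`, `net_std_range`, `mode` (`"hard"` or `"soft"`).
#' @param mask_overlap Fraction of an intracellular ROI's pixels that must lie
#'   inside the NET/artifact mask for the ROI to be ignored (default 0.5; set
#'   to 0 to ignore on any overlap).
#' @param log_sigma LoG scale in pixels (default 2).
#' @param quality_includes_artifacts Whether extracellular artifacts count as
#'   unclassified area in the quality score (default `TRUE`).
#' @return A `netquant_config` list.
#' @export
netquant_config <- function(classes = list(),
                            s = 0.5,
                            assign_threshold = 0.8,
                            reject_threshold = 0.4,
                            segmentation = list(
                              total_dna = list(threshold = 250, min_area = 4,
                                               connectivity = 8,
                                               filter = "none"),
                              extracellular_dna = list(threshold = 250,
                                                       min_area = 4,
                                                       connectivity = 8,
                                                       filter = "none")
                            ),
                            stage1 = list(min_net_area = 300,
                                          net_mean_range = c(300, 5000),
                                          net_std_range = c(150, Inf),
                                          mode = "hard"),
                            mask_overlap = 0.5,
                            log_sigma = 2,
                            quality_includes_artifacts = TRUE) {
  stopifnot(0 <= reject_threshold, reject_threshold <= assign_threshold,
            assign_threshold <= 1, s >= 0,
            mask_overlap >= 0, mask_overlap <= 1,
            stage1$min_net_area >= 1, log_sigma > 0)
  defaults <- list(threshold = 250, min_area = 4, connectivity = 8,
                   filter = "none", sigma = 2, radius = 1)
  for (ch in c("total_dna", "extracellular_dna")) {
    segmentation[[ch]] <- modifyList(defaults, segmentation[[ch]] %||% list())
  }
  cfg <- list(
    classes = classes, s = s,
    assign_threshold = assign_threshold, reject_threshold = reject_threshold,
    segmentation = segmentation, stage1 = stage1,
    mask_overlap = mask_overlap, log_sigma = log_sigma,
    quality_includes_artifacts = quality_includes_artifacts
  )
  structure(cfg, class = "netquant_config")
}

#' Class definitions contained in a configuration
#'
#' @param config A `netquant_config`.
#' @param candidates Optional subset of class names to keep (e.g. the 4-class
#'   benchmark mode); defaults to all configured classes.
#' @return List of [class_definition()]s.
#' @export
config_classes <- function(config, candidates = NULL) {
  nms <- names(config$classes)
  if (!is.null(candidates)) {
    missing <- setdiff(candidates, nms)
    if (length(missing) > 0) {
      stop("configuration error: undefined class(es): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    nms <- candidates
  }
  lapply(nms, function(nm) {
    class_definition(nm, lapply(config$classes[[nm]], as.numeric))
  })
}

#' Read an analysis configuration from YAML
#'
#' The file holds the top-level keys `s`, `assign_threshold`,
#' `reject_threshold`, a `classes` block (one sub-block per class, keys =
#' feature names, values = `[l, u]`), and optional `segmentation`, `stage1`,
#' `mask_overlap`, `log_sigma`, `quality_includes_artifacts` blocks. The
#' strings `"inf"` and `"-inf"` (any case, with or without a leading dot) are
#' accepted as infinite bounds.
#'
#' @param path YAML file path.
#' @return A `netquant_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw <- rapply(raw, parse_inf, how = "replace")
  args <- list(
    classes = raw$classes %||% list(),
    s = raw$s %||% 0.5,
    assign_threshold = raw$assign_threshold %||% 0.8,
    reject_threshold = raw$reject_threshold %||% 0.4,
    mask_overlap = raw$mask_overlap %||% 0.5,
    log_sigma = raw$log_sigma %||% 2,
    quality_includes_artifacts = raw$quality_includes_artifacts %||% TRUE
  )
  if (!is.null(raw$segmentation)) args$segmentation <- raw$segmentation
  if (!is.null(raw$stage1)) {
    s1 <- raw$stage1
    s1$net_mean_range <- as.numeric(unlist(s1$net_mean_range))
    s1$net_std_range <- as.numeric(unlist(s1$net_std_range))
    s1$mode <- s1$mode %||% "hard"
    args$stage1 <- s1
  }
  args$classes <- lapply(args$classes, function(cls) {
    lapply(cls, function(r) as.numeric(unlist(r)))
  })
  do.call(netquant_config, args)
}

parse_inf <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    low <- tolower(trimws(x))
    if (low %in% c("inf", "+inf", ".inf", "infinity")) return(Inf)
    if (low %in% c("-inf", "-.inf", "-infinity")) return(-Inf)
  }
  x
}

#' Write a configuration to YAML
#'
#' Infinite bounds are serialized as the strings `"inf"` / `"-inf"`.
#'
#' @param config A `netquant_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  ser <- rapply(unclass(config), function(x) {
    if (is.numeric(x) && any(is.infinite(x))) {
      x <- as.character(x)
      x[x == "Inf"] <- "inf"
      x[x == "-Inf"] <- "-inf"
    }
    x
  }, how = "replace")
  yaml::write_yaml(ser, path)
  invisible(path)
}
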