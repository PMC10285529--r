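#' Partial membership score of a feature value in an acceptance interval
#'
#' The score is 1 inside `[l, u]` and falls smoothly (half-sine ramps) to 0
#' over adaptive error margins on either side. The margins scale with the
#' interval and its boundary values,
#' \deqn{\Delta_l = s\,l\,(u-l)/(u+l), \qquad \Delta_u = s\,u\,(u-l)/(u+l),}
#' so a single dimensionless margin factor `s` works for all features
#' regardless of their units. Writing \eqn{l_0 = l - \Delta_l} and
#' \eqn{u_0 = u + \Delta_u}:
#' \deqn{S(x) = 1 \textrm{ on } [l,u];\quad
#'   \tfrac12 + \tfrac12\sin\!\big(\pi\,(x-l+\Delta_l)/\Delta_l - \pi/2\big)
#'   \textrm{ on } [l_0, l];}
#' \deqn{\tfrac12 + \tfrac12\sin\!\big(\pi\,(x-u+\Delta_u)/\Delta_u - \pi/2\big)
#'   \textrm{ on } [u, u_0];\quad 0 \textrm{ otherwise.}}
#'
#' Degenerate and extended cases: an infinite bound drops its ramp (the score
#' is 1 on that whole side) and the remaining margin becomes `s * |bound|`;
#' `l = u` or a zero-valued bound gives a hard edge (zero margin) on that
#' side; for intervals containing negative values (possible for the mean-LoG
#' feature) the margin formulas use `|l|` and `|u|`, keeping margins
#' non-negative.
#'
#' @param x Feature value(s); vectorized.
#' @param l,u Lower and upper acceptance bounds (`l <= u`; either may be
#'   infinite).
#' @param s Dimensionless margin factor (`>= 0`); `s = 0` reduces to a hard
#'   interval test.
#' @return Score(s) in `[0, 1]`.
#' @examples
#' partial_score(15, 10, 20, s = 1)          # inside [l, u] -> 1
#' partial_score(10 - 10 / 3, 10, 20, s = 1) # at l - Delta_l -> 0
#' partial_score(25 / 3, 10, 20, s = 1)      # margin midpoint -> 0.5
#' @export
partial_score <- function(x, l, u, s) {
  if (l > u) stop("configuration error: l > u in feature range", call. = FALSE)
  if (s < 0) stop("configuration error: s must be >= 0", call. = FALSE)
  m <- score_margins(l, u, s)
  out <- numeric(length(x))
  inside <- x >= l & x <= u
  out[inside] <- 1

  if (is.finite(l) && m$dl > 0) {
    lo <- x >= l - m$dl & x < l
    out[lo] <- 0.5 + 0.5 * sin(pi * (x[lo] - l + m$dl) / m$dl - pi / 2)
  }
  if (is.finite(u) && m$du > 0) {
    hi <- x > u & x <= u + m$du
    out[hi] <- 0.5 + 0.5 * sin(pi * (x[hi] - u + m$du) / m$du - pi / 2)
  }
  pmin(pmax(out, 0), 1)
}

# Margin widths for an acceptance interval. Magnitudes of the bounds are used
# so that intervals with negative endpoints still get non-negative margins.
score_margins <- function(l, u, s) {
  if (is.infinite(l) && is.infinite(u)) return(list(dl = 0, du = 0))
  if (is.infinite(u)) return(list(dl = s * abs(l), du = 0))
  if (is.infinite(l)) return(list(dl = 0, du = s * abs(u)))
  denom <- abs(l) + abs(u)
  if (denom == 0 || l == u) return(list(dl = 0, du = 0))
  width <- u - l
  list(dl = s * abs(l) * width / denom, du = s * abs(u) * width / denom)
}

#' Define an ROI class by per-feature acceptance intervals
#'
#' @param class_name Class label (e.g. `"PMN"`, `"RUP"`).
#' @param ranges Named list of length-2 numeric vectors `c(l, u)`; names are
#'   feature columns (`area`, `mean_total`, `mean_extra`, `std_extra`,
#'   `mean_log`, `circ_perimeter`, `circ_diameter`). Use `Inf` / `-Inf` for
#'   open-ended bounds. Features without a range do not constrain the class.
#' @return A `class_definition` object.
#' @export
class_definition <- function(class_name, ranges) {
  if (anyDuplicated(names(ranges))) {
    stop("configuration error: duplicate feature in class ", class_name,
         call. = FALSE)
  }
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || !is.numeric(r) || r[1] > r[2]) {
      stop(sprintf("configuration error: invalid range for %s in class %s",
                   nm, class_name), call. = FALSE)
    }
    if (is.infinite(r[1]) && is.infinite(r[2])) {
      stop(sprintf(
        "configuration error: both bounds infinite for %s in class %s",
        nm, class_name), call. = FALSE)
    }
  }
  structure(list(class_name = class_name, ranges = ranges),
            class = "class_definition")
}

#' Class score of a feature vector
#'
#' The product of [partial_score()] over the class's feature ranges; features
#' the class does not constrain contribute a factor of 1. The score is 1 iff
#' every constrained feature lies inside its `[l, u]`.
#'
#' @param fv Named list or one-row data frame of feature values.
#' @param cd A [class_definition()].
#' @param s Margin factor shared by all features.
#' @return Score in `[0, 1]`.
#' @export
class_score <- function(fv, cd, s) {
  score <- 1
  for (nm in names(cd$ranges)) {
    if (!nm %in% names(fv)) {
      stop(sprintf("configuration error: class %s requires unknown feature %s",
                   cd$class_name, nm), call. = FALSE)
    }
    r <- cd$ranges[[nm]]
    score <- score * partial_score(as.numeric(fv[[nm]]), r[1], r[2], s)
  }
  score
}

#' Assign a label from a table of class scores
#'
#' An ROI is assigned to a class when that class's score reaches
#' `assign_threshold` (default 0.8) and every competing class scores at or
#' below `reject_threshold` (default 0.4); both comparisons are closed, so a
#' competitor exactly at the rejection threshold does not block assignment.
#' Otherwise the ROI is flagged unknown, with `ambiguity_reason`
#' `"no_high_score"` when no class reaches the assignment threshold and
#' `"multiple_high_scores"` when the unambiguity condition fails.
#'
#' @param scores Named numeric vector of class scores.
#' @param assign_threshold,reject_threshold Decision thresholds,
#'   `0 <= reject <= assign <= 1`.
#' @param unknown_label Label used when no unambiguous assignment exists.
#' @return List with `label`, `ambiguity_reason` (`"none"` when assigned) and
#'   the input `scores`.
#' @export
decide_label <- function(scores, assign_threshold = 0.8,
                         reject_threshold = 0.4,
                         unknown_label = "UNKNOWN_INTRACELLULAR") {
  stopifnot(length(scores) >= 1L, !is.null(names(scores)),
            reject_threshold <= assign_threshold,
            assign_threshold <= 1, reject_threshold >= 0)
  high <- scores >= assign_threshold
  if (!any(high)) {
    return(list(label = unknown_label, ambiguity_reason = "no_high_score",
                scores = scores))
  }
  if (sum(high) == 1L && all(scores[!high] <= reject_threshold)) {
    return(list(label = names(scores)[high], ambiguity_reason = "none",
                scores = scores))
  }
  list(label = unknown_label, ambiguity_reason = "multiple_high_scores",
       scores = scores)
}

#' Classify feature rows against a set of class definitions
#'
#' Computes every candidate class score for every row and applies the
#' unambiguous-assignment rule of [decide_label()]. The full score table is
#' always returned (`score_<class>` columns) together with the winning
#' `label`, its `score`, and the `ambiguity_reason`.
#'
#' @param features Feature tibble (one row per ROI).
#' @param classes List of [class_definition()]s (the candidate set).
#' @param s Margin factor.
#' @param assign_threshold,reject_threshold Decision thresholds.
#' @param unknown_label Label for unassigned rows.
#' @return `features` with score columns, `label`, `score` and
#'   `ambiguity_reason` appended.
#' @export
classify_features <- function(features, classes, s = 0.5,
                              assign_threshold = 0.8, reject_threshold = 0.4,
                              unknown_label = "UNKNOWN_INTRACELLULAR") {
  stopifnot(length(classes) >= 1L)
  class_names <- vapply(classes, function(cd) cd$class_name, "")
  score_mat <- matrix(NA_real_, nrow(features), length(classes),
                      dimnames = list(NULL, class_names))
  for (j in seq_along(classes)) {
    for (i in seq_len(nrow(features))) {
      score_mat[i, j] <- class_score(features[i, ], classes[[j]], s)
    }
  }
  score_cols <- tibble::as_tibble(score_mat, .name_repair = "minimal")
  names(score_cols) <- paste0("score_", class_names)
  out <- dplyr::bind_cols(features, score_cols)
  if (nrow(features) == 0L) {
    return(dplyr::mutate(out, label = character(0), score = numeric(0),
                         ambiguity_reason = character(0)))
  }
  decisions <- apply(score_mat, 1L, function(sc) {
    d <- decide_label(sc, assign_threshold, reject_threshold, unknown_label)
    c(label = d$label, reason = d$ambiguity_reason)
  })
  out$label <- decisions["label", ]
  out$score <- apply(score_mat, 1L, max)
  out$ambiguity_reason <- decisions["reason", ]
  out
}
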