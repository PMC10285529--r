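# Independent brute-force oracles used to validate the implementation.

# Flood-fill connected-component labelling (BFS), 4- or 8-neighbourhood.
flood_fill_label <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8L) {
    offs <- c(offs, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  }
  k <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    k <- k + 1L
    queue <- start
    lab[start] <- k
    while (length(queue) > 0L) {
      cur <- queue[1L]; queue <- queue[-1L]
      r <- ((cur - 1L) %% nr) + 1L
      c_ <- ((cur - 1L) %/% nr) + 1L
      for (off in offs) {
        r2 <- r + off[1]; c2 <- c_ + off[2]
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc) {
          nb <- (c2 - 1L) * nr + r2
          if (mask[nb] && lab[nb] == 0L) {
            lab[nb] <- k
            queue <- c(queue, nb)
          }
        }
      }
    }
  }
  lab
}

# Canonical partition: sorted pixel indices per component, sorted by first
# pixel, so two labelings can be compared regardless of label numbering.
partition_of <- function(lab) {
  groups <- split(which(lab > 0L), lab[lab > 0L])
  groups <- lapply(groups, sort)
  unname(groups[order(vapply(groups, min, 0L))])
}

# Brute-force median filter with windows clipped at the image border.
brute_median_filter <- function(pixels, radius) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (c_ in seq_len(nc)) {
      rs <- max(1, r - radius):min(nr, r + radius)
      cs <- max(1, c_ - radius):min(nc, c_ + radius)
      out[r, c_] <- stats::median(pixels[rs, cs])
    }
  }
  out
}

# Exhaustive one-to-one matching oracle: over all matchings among candidate
# pairs with IoU >= threshold, maximize the decreasing-sorted IoU sequence
# lexicographically. Returns that sequence.
brute_force_match_seq <- function(preds, truths, iou_threshold = 0.10) {
  np <- nrow(preds); nt <- nrow(truths)
  if (np == 0L || nt == 0L) return(numeric(0))
  pb <- as.matrix(preds[, c("rmin", "cmin", "rmax", "cmax")])
  tb <- as.matrix(truths[, c("rmin", "cmin", "rmax", "cmax")])
  cand <- expand.grid(p = seq_len(np), t = seq_len(nt))
  cand$iou <- mapply(function(i, j) box_iou(pb[i, ], tb[j, ]),
                     cand$p, cand$t)
  cand <- cand[cand$iou >= iou_threshold, , drop = FALSE]
  if (nrow(cand) == 0L) return(numeric(0))

  lex_greater <- function(a, b) {
    n <- max(length(a), length(b))
    a <- c(a, rep(-1, n - length(a)))
    b <- c(b, rep(-1, n - length(b)))
    d <- a - b
    nz <- which(d != 0)
    length(nz) > 0 && d[nz[1]] > 0
  }
  best <- numeric(0)
  recurse <- function(k, used_p, used_t, seq_so_far) {
    if (k > nrow(cand)) {
      s <- sort(seq_so_far, decreasing = TRUE)
      if (lex_greater(s, best)) best <<- s
      return(invisible())
    }
    recurse(k + 1L, used_p, used_t, seq_so_far)  # skip pair k
    i <- cand$p[k]; j <- cand$t[k]
    if (!used_p[i] && !used_t[j]) {
      used_p[i] <- TRUE; used_t[j] <- TRUE
      recurse(k + 1L, used_p, used_t, c(seq_so_far, cand$iou[k]))
    }
  }
  recurse(1L, logical(np), logical(nt), numeric(0))
  best
}

# Continuous coordinates: exact IoU ties (where greedy tie-breaking is
# deliberately arbitrary) have probability zero.
random_boxes <- function(n, extent = 20) {
  tibble::tibble(
    rmin = runif(n, 0, extent - 2),
    cmin = runif(n, 0, extent - 2)
  ) |>
    dplyr::mutate(
      rmax = .data$rmin + runif(n, 0.5, 6),
      cmax = .data$cmin + runif(n, 0.5, 6)
    )
}
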