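# Correspondence analysis of the site-by-species matrix, with optional
# Hill-style detrending by segments of axis 1 (the arch-removal step of
# detrended correspondence analysis; no nonlinear rescaling).

#' Correspondence analysis of a community matrix
#'
#' Singular value decomposition of the standardized residual table
#' `diag(1/sqrt(r)) (P - r c') diag(1/sqrt(c))` where `P` is the matrix of
#' relative frequencies and `r`, `c` its row and column masses. Eigenvalues
#' are squared singular values; the variance explained by an axis is its
#' eigenvalue over the total inertia. Site (row) scores are in principal
#' coordinates, species (column) scores in standard coordinates. All-zero
#' rows or columns are dropped with a warning.
#'
#' @param community a `community_matrix` (or non-negative matrix).
#' @param n_axes number of axes to keep (default 4, capped by rank).
#' @return an `ordination_result`: list with `site_scores`,
#'   `species_scores` (matrices, one column per axis), `eigenvalues`,
#'   `variance_fraction`, `detrended = FALSE`, `n_segments = NA`.
#' @export
correspondence_analysis <- function(community, n_axes = 4) {
  m <- unclass(as.matrix(community))
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("community matrix must be non-negative")
  zr <- rowSums(m) == 0; zc <- colSums(m) == 0
  if (any(zr)) {
    warning("dropping ", sum(zr), " all-zero site row(s): ",
            paste(rownames(m)[zr], collapse = ", "))
    m <- m[!zr, , drop = FALSE]
  }
  if (any(zc)) {
    warning("dropping ", sum(zc), " all-zero species column(s)")
    m <- m[, !zc, drop = FALSE]
  }
  if (nrow(m) < 2) stop("need at least 2 non-zero site rows")
  P <- m / sum(m)
  r <- rowSums(P); cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cc)) %*% diag(1 / sqrt(cc))
  sv <- svd(S)
  lambda <- sv$d^2
  nk <- min(n_axes, sum(lambda > 1e-12))
  if (nk < 1) stop("community matrix has no compositional variation")
  idx <- seq_len(nk)
  # rows in principal coordinates, columns in standard coordinates
  site_scores <- diag(1 / sqrt(r)) %*% sv$u[, idx, drop = FALSE] %*%
    diag(sv$d[idx], nk, nk)
  species_scores <- diag(1 / sqrt(cc)) %*% sv$v[, idx, drop = FALSE]
  dimnames(site_scores) <- list(rownames(m), paste0("CA", idx))
  dimnames(species_scores) <- list(colnames(m), paste0("CA", idx))
  structure(list(site_scores = site_scores,
                 species_scores = species_scores,
                 eigenvalues = lambda[idx],
                 total_inertia = sum(lambda),
                 variance_fraction = lambda[idx] / sum(lambda),
                 detrended = FALSE, n_segments = NA_integer_),
            class = "ordination_result")
}

#' Detrend the second ordination axis by segments
#'
#' Removes the arch artefact of correspondence analysis by centering the
#' axis-2 site scores within equal-width windows of axis 1 (Hill's
#' detrending-by-segments; no nonlinear rescaling). Segments holding fewer
#' than 2 sites are merged with their neighbour, with a warning. Axis-1
#' scores and species scores are left unchanged.
#'
#' @param result an `ordination_result` with at least 2 axes.
#' @param n_segments number of axis-1 segments (default 26).
#' @return the modified `ordination_result` with `detrended = TRUE` and the
#'   realized `n_segments`.
#' @export
detrend_axis <- function(result, n_segments = 26) {
  stopifnot(inherits(result, "ordination_result"))
  if (ncol(result$site_scores) < 2)
    stop("detrending needs at least 2 computed axes")
  a1 <- result$site_scores[, 1]
  a2 <- result$site_scores[, 2]
  n_segments <- max(1L, as.integer(n_segments))
  breaks <- seq(min(a1), max(a1), length.out = n_segments + 1)
  breaks[1] <- breaks[1] - 1e-9; breaks[n_segments + 1] <- breaks[n_segments + 1] + 1e-9
  seg <- cut(a1, breaks = breaks, labels = FALSE)
  # merge undersized segments into their left neighbour (leftmost merges right)
  counts <- tabulate(seg, nbins = n_segments)
  used <- which(counts > 0)
  if (any(counts[used] < 2) && length(used) > 1) {
    warning("merging segments with fewer than 2 sites")
    repeat {
      counts <- table(seg)
      small <- names(counts)[counts < 2]
      if (length(small) == 0 || length(counts) == 1) break
      s <- as.integer(small[1])
      lv <- sort(unique(seg))
      tgt <- if (any(lv < s)) max(lv[lv < s]) else min(lv[lv > s])
      seg[seg == s] <- tgt
    }
  }
  a2d <- a2
  for (s in unique(seg)) {
    idx <- seg == s
    a2d[idx] <- a2[idx] - mean(a2[idx])
  }
  result$site_scores[, 2] <- a2d
  result$detrended <- TRUE
  result$n_segments <- length(unique(seg))
  result
}

#' @export
print.ordination_result <- function(x, ...) {
  cat("<ordination_result>", if (x$detrended) "(detrended)", "\n")
  cat("eigenvalues:", paste(round(x$eigenvalues, 4), collapse = ", "), "\n")
  cat("variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_fraction), collapse = ", "),
      "\n")
  invisible(x)
}
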