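# Spatial-dependence screening: empirical semivariogram with a Monte-Carlo
# permutation envelope under complete spatial randomness of the values.

pair_structure <- function(sites, n_bins, max_lag = NULL) {
  n <- nrow(sites)
  if (n < 2) stop("need at least 2 sites")
  d <- as.matrix(site_distances(sites))
  ij <- which(upper.tri(d), arr.ind = TRUE)
  dd <- d[upper.tri(d)]
  if (all(dd == 0)) stop("all sites are co-located; semivariogram undefined")
  if (is.null(max_lag)) max_lag <- max(dd) / 2
  keep <- dd > 0 & dd <= max_lag
  breaks <- seq(0, max_lag, length.out = n_bins + 1)
  bin <- cut(dd[keep], breaks = breaks, include.lowest = FALSE,
             labels = FALSE)
  list(i = ij[keep, 1], j = ij[keep, 2], bin = bin, breaks = breaks,
       centre = (breaks[-1] + breaks[-(n_bins + 1)]) / 2)
}

gamma_from_pairs <- function(values, ps, n_bins) {
  sq <- (values[ps$i] - values[ps$j])^2
  npairs <- tabulate(ps$bin, nbins = n_bins)
  gsum <- vapply(seq_len(n_bins), function(b) sum(sq[ps$bin == b]), 0)
  list(gamma = ifelse(npairs > 0, gsum / (2 * npairs), NA_real_),
       n_pairs = npairs)
}

#' Empirical semivariogram of a site-level response
#'
#' For each distance bin `h`, `gamma(h) = sum over site pairs in the bin of
#' (z_i - z_j)^2 / (2 * N_h)`. Bins are equal-width up to half the maximum
#' intersite distance (configurable); pairs beyond the maximum lag are
#' ignored.
#'
#' @param sites a `site_table` with distinct coordinates.
#' @param values a `response_vector` or numeric vector in site order.
#' @param n_bins number of lag bins (default 6).
#' @param max_lag maximum lag in metres (default: half the maximum
#'   intersite distance).
#' @return a `semivariogram`: data frame (lag_lower, lag_upper, lag_centre,
#'   gamma, n_pairs) with attribute `flagged = NA` (no envelope computed).
#' @export
empirical_semivariogram <- function(sites, values, n_bins = 6,
                                    max_lag = NULL) {
  if (inherits(values, "response_vector")) values <- values$values
  if (length(values) != nrow(sites))
    stop("values length does not match number of sites")
  ps <- pair_structure(sites, n_bins, max_lag)
  g <- gamma_from_pairs(as.numeric(values), ps, n_bins)
  out <- data.frame(
    lag_lower = ps$breaks[-(n_bins + 1)], lag_upper = ps$breaks[-1],
    lag_centre = ps$centre, gamma = g$gamma, n_pairs = g$n_pairs)
  structure(out, class = c("semivariogram", "data.frame"), flagged = NA)
}

#' Monte-Carlo envelope test for spatial dependence
#'
#' Builds a pointwise confidence envelope for the semivariogram under
#' complete spatial randomness by permuting the observed values across the
#' site locations `n_sim` times (the permutation preserves the multiset of
#' values, so mean and variance of each simulated dataset equal the
#' observed ones) and taking pointwise `alpha/2` and `1 - alpha/2`
#' quantiles per bin. The response is flagged as spatially correlated when
#' the observed semivariance leaves the envelope in any bin (default rule)
#' or in two consecutive bins (`rule = "consecutive2"`).
#'
#' @inheritParams empirical_semivariogram
#' @param n_sim number of permutations (default 1000; at least 99).
#' @param alpha envelope level (default 0.05).
#' @param rule excursion rule: `"any"` (default) or `"consecutive2"`.
#' @return a `semivariogram` data frame with `envelope_low`,
#'   `envelope_high` and `outside` columns and attribute `flagged`.
#' @export
mc_envelope_test <- function(sites, values, n_sim = 1000, alpha = 0.05,
                             n_bins = 6, max_lag = NULL,
                             rule = c("any", "consecutive2")) {
  rule <- match.arg(rule)
  if (inherits(values, "response_vector")) values <- values$values
  values <- as.numeric(values)
  if (n_sim < 99)
    stop("n_sim must be at least 99 for alpha = ", alpha, " quantiles")
  if (n_sim * alpha / 2 < 1)
    stop("n_sim too small for the requested alpha")
  ps <- pair_structure(sites, n_bins, max_lag)
  obs <- gamma_from_pairs(values, ps, n_bins)

  # vectorized over permutations: one (n_pairs x n_sim) matrix of squared
  # differences, reduced per bin
  perm <- vapply(seq_len(n_sim), function(s) sample(values), values)
  sq <- (perm[ps$i, , drop = FALSE] - perm[ps$j, , drop = FALSE])^2
  npairs <- tabulate(ps$bin, nbins = n_bins)
  gsim <- rowsum(sq, group = ps$bin, reorder = TRUE)
  gam_sim <- matrix(NA_real_, n_bins, n_sim)
  present <- sort(unique(ps$bin))
  gam_sim[present, ] <- gsim / (2 * npairs[present])

  lo <- apply(gam_sim, 1, quantile, probs = alpha / 2, na.rm = TRUE,
              names = FALSE)
  hi <- apply(gam_sim, 1, quantile, probs = 1 - alpha / 2, na.rm = TRUE,
              names = FALSE)
  outside <- !is.na(obs$gamma) & (obs$gamma < lo | obs$gamma > hi)
  flagged <- if (rule == "any") any(outside, na.rm = TRUE)
             else any(outside[-1] & outside[-length(outside)], na.rm = TRUE)
  out <- data.frame(
    lag_lower = ps$breaks[-(n_bins + 1)], lag_upper = ps$breaks[-1],
    lag_centre = ps$centre, gamma = obs$gamma, n_pairs = obs$n_pairs,
    envelope_low = lo, envelope_high = hi, outside = outside)
  structure(out, class = c("semivariogram", "data.frame"),
            flagged = flagged, n_sim = n_sim, alpha = alpha, rule = rule)
}

#' Was a response flagged as spatially correlated?
#'
#' @param x a `semivariogram` from [mc_envelope_test()].
#' @return logical flag (or `NA` if no envelope was computed).
#' @export
is_flagged <- function(x) {
  stopifnot(inherits(x, "semivariogram"))
  attr(x, "flagged")
}
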