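# Scale of effect: which buffer radius best captures the cover-response
# association, ranked by Spearman correlation across the candidate radii.

#' Area of a circular landscape buffer
#'
#' @param radius buffer radius in metres (vectorized).
#' @return area in hectares, `pi * radius^2 / 10000`. The standard radii
#'   500, 1000, 1500 and 2000 m give 78.54, 314.16, 706.86 and 1256.64 ha.
#' @export
landscape_area <- function(radius) {
  if (any(radius < 0)) stop("radius must be >= 0")
  pi * radius^2 / 1e4
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties (Pearson correlation of
#' the average-rank transforms). Constant input gives `NA` with a warning.
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return scalar correlation in [-1, 1], or `NA`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("spearman_rho undefined for constant input; returning NA")
    return(NA_real_)
  }
  unname(cor(x, y, method = "spearman"))
}

#' Select the scale of effect for one response
#'
#' Computes the Spearman correlation between the response and percent
#' forest cover at every buffer radius in the site table and picks the
#' radius with the strongest association. By default the absolute
#' correlation is maximized, so declining and increasing responses are
#' treated symmetrically; ties are broken toward the smaller (more local)
#' radius.
#'
#' @param response a `response_vector` (see [aggregate_response()]) or a
#'   plain numeric vector in site-table order.
#' @param sites a `site_table`.
#' @param use_abs maximize `|rho|` (default) rather than signed `rho`.
#' @return a `scale_selection`: list with `label`, `rho_by_radius` (named
#'   numeric, names = radii in m) and `best_radius`.
#' @export
select_scale <- function(response, sites, use_abs = TRUE) {
  values <- if (inherits(response, "response_vector")) response$values
            else response
  label <- if (inherits(response, "response_vector")) response$label else "response"
  if (length(values) != nrow(sites))
    stop("response length does not match number of sites")
  if (nrow(sites) < 3) stop("need at least 3 sites")
  radii <- site_radii(sites)
  rho <- vapply(radii, function(r) {
    suppressWarnings(spearman_rho(site_cover(sites, r), values))
  }, numeric(1))
  names(rho) <- radii
  score <- if (use_abs) abs(rho) else rho
  if (all(is.na(score))) {
    warning("all correlations undefined; returning smallest radius")
    best <- radii[1]
  } else {
    best <- radii[which.max(score)]  # which.max: first max -> smaller radius
  }
  structure(list(label = label, rho_by_radius = rho, best_radius = best),
            class = "scale_selection")
}

#' @export
print.scale_selection <- function(x, ...) {
  cat("<scale_selection> ", x$label, "\n", sep = "")
  print(round(x$rho_by_radius, 3))
  cat("best radius:", x$best_radius, "m\n")
  invisible(x)
}

#' Scale-of-effect summary across a set of responses
#'
#' Applies [select_scale()] to every response and reports, per radius and
#' response kind, the fraction of responses for which that radius wins
#' (a "1000 m ranked highest for X% of richness models"-style
#' summary), plus an overall chosen radius (the radius winning most
#' responses, ties toward the smaller radius).
#'
#' @param responses list of `response_vector`s.
#' @param sites a `site_table`.
#' @param use_abs passed to [select_scale()].
#' @return list with `per_response` (data frame: label, kind, best_radius
#'   and rho per radius), `winning_fraction` (data frame: kind, radius,
#'   fraction) and `chosen_radius`.
#' @export
scale_summary <- function(responses, sites, use_abs = TRUE) {
  radii <- site_radii(sites)
  sel <- lapply(responses, select_scale, sites = sites, use_abs = use_abs)
  kinds <- vapply(responses, function(r)
    if (inherits(r, "response_vector")) r$kind else "response", "")
  per <- data.frame(
    label = vapply(sel, `[[`, "", "label"),
    kind = kinds,
    best_radius = vapply(sel, `[[`, 0, "best_radius"),
    stringsAsFactors = FALSE)
  rho_mat <- t(vapply(sel, `[[`, numeric(length(radii)), "rho_by_radius"))
  colnames(rho_mat) <- paste0("rho_", radii)
  per <- cbind(per, as.data.frame(rho_mat))
  rownames(per) <- NULL
  wf <- do.call(rbind, lapply(unique(kinds), function(kk) {
    wins <- per$best_radius[per$kind == kk]
    data.frame(kind = kk, radius = radii,
               fraction = vapply(radii, function(r) mean(wins == r), 0))
  }))
  tot <- table(factor(per$best_radius, levels = radii))
  chosen <- radii[which.max(tot)]
  list(per_response = per, winning_fraction = wf, chosen_radius = chosen)
}
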