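# Spatial linear models: Gaussian GLS with exponential spatial covariance,
# Sigma_ij = tau2 * 1[i = j] + sill * exp(-d_ij / phi), all parameters
# (mean and covariance) estimated jointly by maximum likelihood so AICc is
# comparable across mean structures. The logistic mean is deliberately not
# supported on this path.

exp_covariance <- function(d, phi, tau2, sill) {
  S <- sill * exp(-d / phi)
  diag(S) <- diag(S) + tau2
  S
}

mvn_nll <- function(r, S) {
  ch <- try(chol(S), silent = TRUE)
  if (inherits(ch, "try-error")) {
    ch <- try(chol(S + diag(1e-8 * mean(diag(S)), nrow(S))), silent = TRUE)
    if (inherits(ch, "try-error")) return(1e10)
  }
  z <- backsolve(ch, r, transpose = TRUE)
  0.5 * (length(r) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

spatial_mean <- function(model, th, x) {
  switch(model,
    null = rep(th[1], length(x)),
    linear = th[1] + th[2] * x,
    power = {
      if (any(x <= 0)) stop("power-law model requires x > 0")
      th[1] * x^th[2]
    })
}

#' Fit a spatial linear model (GLS with exponential covariance)
#'
#' Fits one of the null, linear or power-law mean functions with a
#' spatially correlated Gaussian error: covariance
#' `tau2 * I + sill * exp(-d/phi)` over intersite distances `d` (metres),
#' with nugget `tau2`, partial sill and range `phi` estimated jointly with
#' the mean parameters by maximum likelihood. The four-parameter logistic
#' is excluded from this candidate set (it does not adjust reliably under
#' the spatial likelihood), so flagged responses are compared over exactly
#' three models. `k` counts the mean parameters plus the three covariance
#' parameters.
#'
#' @param model `"null"`, `"linear"` or `"power"` (`"logistic4p"` errors).
#' @param x predictor values (percent cover).
#' @param y response values.
#' @param sites a `site_table` with distinct coordinates.
#' @param n_restarts jittered optimizer starts (default 5).
#' @param fixed_cov optional list `(phi, tau2, sill)` fixing the covariance
#'   (then only mean parameters are estimated and `k` counts them plus the
#'   fixed covariance parameters are excluded).
#' @return a `model_fit` (see [fit_candidate()]) with extra fields `phi`,
#'   `tau2`, `sill` and `cov_family = "exponential"`.
#' @export
fit_spatial_linear <- function(model, x, y, sites, n_restarts = 5,
                               fixed_cov = NULL) {
  if (identical(model, "logistic4p"))
    stop("logistic4p is excluded from spatial linear models; ",
         "only null, linear and power means are supported")
  model <- match.arg(model, c("null", "linear", "power"))
  stopifnot(length(x) == nrow(sites), length(y) == nrow(sites))
  d <- as.matrix(site_distances(sites))
  if (any(d[upper.tri(d)] == 0))
    stop("sites must have distinct coordinates")
  n <- length(y)
  n_mean <- if (model == "null") 1L else 2L
  est_cov <- is.null(fixed_cov)
  k <- n_mean + if (est_cov) 3L else 0L

  mean_start <- switch(model,
    null = mean(y),
    linear = unname(coef(lm(y ~ x))),
    power = unname(start_values("power", x, y)))

  obj <- function(p) {
    thm <- p[seq_len(n_mean)]
    if (est_cov) {
      phi <- exp(p[n_mean + 1]); tau2 <- exp(p[n_mean + 2])
      sill <- exp(p[n_mean + 3])
    } else {
      phi <- fixed_cov$phi; tau2 <- fixed_cov$tau2; sill <- fixed_cov$sill
    }
    mu <- try(spatial_mean(model, thm, x), silent = TRUE)
    if (inherits(mu, "try-error") || any(!is.finite(mu))) return(1e10)
    S <- exp_covariance(d, phi, max(tau2, 0), max(sill, 0))
    if (max(tau2, 0) + max(sill, 0) <= 0) return(1e10)
    mvn_nll(y - mu, S)
  }

  v <- var(y)
  p0 <- c(mean_start,
          if (est_cov) c(log(median(d[upper.tri(d)]) / 3),
                         log(v / 2 + 1e-8), log(v / 2 + 1e-8)))
  best <- NULL
  for (i in seq_len(n_restarts)) {
    p <- if (i == 1) p0 else p0 * (1 + 0.3 * rnorm(length(p0))) +
      c(rep(0.05 * sd(y), n_mean), if (est_cov) rnorm(3, 0, 0.7))
    opt <- try(optim(p, obj, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-10)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("spatial fit failed on all starts")

  thm <- best$par[seq_len(n_mean)]
  names(thm) <- mean_par_names(model)
  if (est_cov) {
    phi <- exp(best$par[n_mean + 1]); tau2 <- exp(best$par[n_mean + 2])
    sill <- exp(best$par[n_mean + 3])
  } else {
    phi <- fixed_cov$phi; tau2 <- fixed_cov$tau2; sill <- fixed_cov$sill
  }
  ll <- -best$value
  conv <- best$convergence == 0 && is.finite(ll)
  structure(list(model = model, theta = thm, family = "gaussian-spatial",
                 logLik = ll, k = k, n = n,
                 AICc = if (n - k - 1 > 0) aicc(ll, k, n) else NA_real_,
                 converged = conv,
                 reason = if (conv) "ok" else "optimizer did not converge",
                 restarts_used = n_restarts,
                 phi = phi, tau2 = tau2, sill = sill,
                 cov_family = "exponential", x = x, y = y),
            class = c("spatial_fit", "model_fit"))
}

#' Rank the three spatial candidate models
#'
#' The dAICc / wAICc bookkeeping of [rank_models()] applied to the
#' restricted null / linear / power spatial candidate set.
#'
#' @param fits list of [fit_spatial_linear()] results.
#' @param cutoff dAICc cutoff (default 2).
#' @return a `model_ranking`; see [rank_models()].
#' @export
rank_spatial_models <- function(fits, cutoff = 2) {
  rank_models(fits, cutoff = cutoff)
}

#' Fit and rank all three spatial candidates for one response
#'
#' @inheritParams fit_spatial_linear
#' @param cutoff dAICc cutoff (default 2).
#' @return a `model_ranking` over the null, linear and power spatial fits.
#' @export
fit_spatial_models <- function(x, y, sites, cutoff = 2, n_restarts = 5) {
  models <- c("null", "linear", "power")
  if (any(x <= 0)) models <- setdiff(models, "power")
  fits <- lapply(models, function(m)
    fit_spatial_linear(m, x, y, sites, n_restarts = n_restarts))
  rank_models(fits, cutoff = cutoff)
}
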