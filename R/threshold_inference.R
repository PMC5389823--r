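# Four-model maximum-likelihood engine: null, linear, power-law and
# four-parameter logistic mean functions; Gaussian (default) or Poisson
# likelihood; AICc ranking with the dAICc <= 2 parsimonious-set rule;
# extinction threshold = logistic inflection point with profile-likelihood CI.

CANDIDATE_MODELS <- c("null", "linear", "power", "logistic4p")

mean_par_names <- function(model) {
  switch(model,
         null = "c",
         linear = c("b0", "b1"),
         power = c("a", "b"),
         logistic4p = c("L", "U", "x0", "s"),
         stop("unknown model '", model, "'"))
}

#' Evaluate a candidate mean function
#'
#' Mean functions of percent forest cover `x`:
#' null `mu = c`; linear `mu = b0 + b1*x`; power law `mu = a*x^b`;
#' four-parameter logistic `mu = L + (U - L) / (1 + exp((x0 - x)/s))`,
#' where `L` and `U` are the asymptotes, `x0` the inflection point (the
#' extinction threshold when the response collapses at low cover) and
#' `s > 0` the scale controlling how fast the curve moves between
#' asymptotes. At `x = x0` the logistic equals `(L + U)/2`.
#'
#' @param model one of `"null"`, `"linear"`, `"power"`, `"logistic4p"`.
#' @param theta named numeric vector of mean parameters (see above).
#' @param x predictor values (percent cover); the power law requires `x > 0`.
#' @return numeric vector `mu(x; theta)`.
#' @export
model_predict <- function(model, theta, x) {
  pn <- mean_par_names(model)
  if (!all(pn %in% names(theta)))
    stop("theta must contain parameter(s): ", paste(pn, collapse = ", "))
  th <- theta[pn]
  switch(model,
    null = rep(unname(th["c"]), length(x)),
    linear = unname(th["b0"] + th["b1"] * x),
    power = {
      if (any(x <= 0)) stop("power-law model requires x > 0")
      unname(th["a"] * x^th["b"])
    },
    logistic4p = {
      if (th["s"] <= 0) stop("logistic scale parameter s must be > 0")
      unname(th["L"] + (th["U"] - th["L"]) /
               (1 + exp((th["x0"] - x) / th["s"])))
    })
}

#' Negative log-likelihood of a candidate model
#'
#' Gaussian: `sum(log(2*pi*sigma^2)/2 + (y - mu)^2/(2*sigma^2))`, with
#' `sigma` supplied in `theta`. Poisson: `sum(mu - y*log(mu) + log(y!))`,
#' requiring `mu > 0`.
#'
#' @inheritParams model_predict
#' @param theta mean parameters plus, for the Gaussian family, `sigma > 0`.
#' @param y observed response values.
#' @param family `"gaussian"` or `"poisson"`.
#' @return scalar negative log-likelihood.
#' @export
neg_log_likelihood <- function(model, theta, x, y,
                               family = c("gaussian", "poisson")) {
  family <- match.arg(family)
  mu <- model_predict(model, theta, x)
  if (family == "gaussian") {
    sigma <- theta[["sigma"]]
    if (is.null(sigma) || !is.finite(sigma) || sigma <= 0)
      stop("gaussian family requires theta['sigma'] > 0")
    sum(0.5 * log(2 * pi * sigma^2) + (y - mu)^2 / (2 * sigma^2))
  } else {
    if (any(mu <= 0)) stop("poisson family requires mu > 0 at every point")
    sum(mu - y * log(mu) + lgamma(y + 1))
  }
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2*logLik + 2k + 2k(k+1)/(n - k - 1)`; requires `n > k + 1`.
#'
#' @param logLik maximized log-likelihood.
#' @param k number of estimated parameters (including the error parameter
#'   for Gaussian fits).
#' @param n number of observations.
#' @return scalar AICc.
#' @export
aicc <- function(logLik, k, n) {
  if (n - k - 1 <= 0)
    stop("AICc undefined: need n > k + 1 (n = ", n, ", k = ", k, ")")
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Concentrated Gaussian nll over the mean parameters: sigma^2 profiled out
# analytically as the mean squared residual (ML estimate).
conc_nll_gaussian <- function(model, th, x, y) {
  mu <- try(model_predict(model, th, x), silent = TRUE)
  if (inherits(mu, "try-error") || any(!is.finite(mu))) return(1e10)
  s2 <- max(mean((y - mu)^2), 1e-12)
  0.5 * length(y) * (log(2 * pi * s2) + 1)
}

# Jacobian d mu / d theta (n x p), for gradient-based optimization
mean_jacobian <- function(model, th, x) {
  switch(model,
    null = matrix(1, length(x), 1),
    linear = cbind(1, x),
    power = {
      xb <- x^th["b"]
      cbind(xb, th["a"] * xb * log(x))
    },
    logistic4p = {
      p <- 1 / (1 + exp((th["x0"] - x) / th["s"]))
      q <- p * (1 - p); dU <- th["U"] - th["L"]
      cbind(1 - p, p, -dU * q / th["s"],
            dU * q * (th["x0"] - x) / th["s"]^2)
    })
}

conc_grad_gaussian <- function(model, th, x, y) {
  mu <- try(model_predict(model, th, x), silent = TRUE)
  if (inherits(mu, "try-error") || any(!is.finite(mu)))
    return(rep(0, length(th)))
  r <- y - mu
  s2 <- max(mean(r^2), 1e-12)
  as.numeric(-crossprod(mean_jacobian(model, th, x), r)) / s2
}

grad_poisson <- function(model, th, x, y) {
  mu <- try(model_predict(model, th, x), silent = TRUE)
  if (inherits(mu, "try-error") || any(!is.finite(mu)) || any(mu <= 0))
    return(rep(0, length(th)))
  as.numeric(crossprod(mean_jacobian(model, th, x), 1 - y / mu))
}

nll_poisson <- function(model, th, x, y) {
  mu <- try(model_predict(model, th, x), silent = TRUE)
  if (inherits(mu, "try-error") || any(!is.finite(mu)) || any(mu <= 0))
    return(1e10)
  sum(mu - y * log(mu) + lgamma(y + 1))
}

start_values <- function(model, x, y) {
  switch(model,
    null = c(c = mean(y)),
    linear = {
      cf <- coef(lm(y ~ x))
      c(b0 = unname(cf[1]), b1 = unname(cf[2]))
    },
    power = {
      ok <- x > 0 & y > 0
      if (sum(ok) >= 3) {
        cf <- coef(lm(log(y[ok]) ~ log(x[ok])))
        c(a = exp(unname(cf[1])), b = unname(cf[2]))
      } else c(a = max(mean(y), 0.1) / max(mean(x), 1), b = 1)
    },
    logistic4p = c(L = min(y), U = max(y), x0 = median(x),
                   s = max(diff(range(x)) / 4, 1e-2)))
}

model_bounds <- function(model, x, y) {
  ry <- max(diff(range(y)), 1e-6); rx <- max(diff(range(x)), 1e-6)
  switch(model,
    null = list(lower = min(y) - 2 * ry, upper = max(y) + 2 * ry),
    linear = list(lower = c(-Inf, -Inf), upper = c(Inf, Inf)),
    power = list(lower = c(1e-10, -10), upper = c(1e8, 10)),
    logistic4p = list(
      lower = c(min(y) - 2 * ry, min(y) - 2 * ry, min(x), rx * 1e-4),
      upper = c(max(y) + 2 * ry, max(y) + 2 * ry, max(x), 4 * rx)))
}

jitter_start <- function(start, bounds, x, y) {
  th <- start * (1 + 0.3 * rnorm(length(start))) +
    0.05 * diff(range(y)) * rnorm(length(start))
  if ("x0" %in% names(start))
    th["x0"] <- runif(1, min(x), max(x))
  if ("s" %in% names(start))
    th["s"] <- runif(1, 0.02, 0.5) * diff(range(x))
  pmin(pmax(th, bounds$lower + 1e-9), bounds$upper - 1e-9)
}

at_bounds <- function(th, bounds) {
  tol <- 1e-5 * pmax(1, abs(bounds$upper - bounds$lower))
  fin <- is.finite(bounds$lower) | is.finite(bounds$upper)
  any(fin & (th - bounds$lower < tol | bounds$upper - th < tol))
}

hessian_ok <- function(fn, th) {
  H <- try(optimHess(th, fn), silent = TRUE)
  if (inherits(H, "try-error") || any(!is.finite(H))) return(FALSE)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  all(ev > 0) && (max(ev) / min(ev) < 1e12)
}

default_restarts <- function(model)
  switch(model, logistic4p = 20, power = 5, 1)

#' Fit one candidate cover-response model by maximum likelihood
#'
#' Minimizes the negative log-likelihood with bounded numerical
#' optimization (`L-BFGS-B`), starting from data-driven values (null: mean;
#' linear: least squares; power: log-log regression; logistic: asymptotes at
#' the response range, inflection at the median cover) plus `n_restarts - 1`
#' jittered starts. For the Gaussian family `sigma` is concentrated out
#' analytically; the returned parameter vector includes its ML estimate.
#' The fit is flagged non-convergent when the optimizer fails, an estimate
#' lands on a bound, or the Hessian at the optimum is not finite and
#' positive definite; non-convergent fits are excluded from ranking.
#'
#' @inheritParams model_predict
#' @param y observed response values.
#' @param family `"gaussian"` or `"poisson"`.
#' @param n_restarts number of optimizer starts (default 20 for the
#'   logistic, 5 for the power law, 1 otherwise).
#' @return an object of class `model_fit`: list with `model`, `theta`,
#'   `family`, `logLik`, `k`, `n`, `AICc`, `converged`, `reason`,
#'   `restarts_used`, `x`, `y`.
#' @export
fit_candidate <- function(model, x, y, family = c("gaussian", "poisson"),
                          n_restarts = NULL) {
  family <- match.arg(family)
  model <- match.arg(model, CANDIDATE_MODELS)
  stopifnot(length(x) == length(y), length(x) >= 3)
  n <- length(y)
  k <- length(mean_par_names(model)) + as.integer(family == "gaussian")
  if (is.null(n_restarts)) n_restarts <- default_restarts(model)

  failed <- function(reason) {
    structure(list(model = model, theta = NULL, family = family,
                   logLik = NA_real_, k = k, n = n, AICc = NA_real_,
                   converged = FALSE, reason = reason, restarts_used = 0L,
                   x = x, y = y), class = "model_fit")
  }
  if (model != "null" && diff(range(x)) == 0)
    return(failed("degenerate predictor: x is constant"))
  if (model == "power" && any(x <= 0))
    return(failed("power-law model requires x > 0"))

  pn <- mean_par_names(model)
  fn <- if (family == "gaussian") {
    function(th) conc_nll_gaussian(model, setNames(th, pn), x, y)
  } else {
    function(th) nll_poisson(model, setNames(th, pn), x, y)
  }
  gr <- if (family == "gaussian") {
    function(th) conc_grad_gaussian(model, setNames(th, pn), x, y)
  } else {
    function(th) grad_poisson(model, setNames(th, pn), x, y)
  }
  bounds <- model_bounds(model, x, y)
  start <- start_values(model, x, y)
  start <- pmin(pmax(start, bounds$lower + 1e-9), bounds$upper - 1e-9)

  best <- NULL
  for (i in seq_len(n_restarts)) {
    th0 <- if (i == 1) start else jitter_start(start, bounds, x, y)
    opt <- try(optim(th0, fn, gr, method = "L-BFGS-B",
                     lower = bounds$lower, upper = bounds$upper,
                     control = list(maxit = 500)), silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) return(failed("optimizer failed on all starts"))

  th <- setNames(best$par, mean_par_names(model))
  # line-search aborts at an (near-)optimal point still count as converged
  g <- gr(best$par)
  g[best$par <= bounds$lower + 1e-9 & g > 0] <- 0
  g[best$par >= bounds$upper - 1e-9 & g < 0] <- 0
  opt_ok <- best$convergence == 0 ||
    max(abs(g)) < 1e-3 * max(1, abs(best$value))
  # an (essentially) interpolating fit makes the concentrated surface
  # non-quadratic at the sigma^2 floor; skip the curvature screen there
  perfect <- family == "gaussian" &&
    mean((y - model_predict(model, th, x))^2) < 1e-10 * max(1, var(y))
  conv <- (opt_ok || perfect) && !at_bounds(best$par, bounds) &&
    (perfect || hessian_ok(fn, best$par))
  reason <- if (conv) "ok"
    else if (!opt_ok) "optimizer did not converge"
    else if (at_bounds(best$par, bounds)) "estimate at parameter bound"
    else "ill-conditioned or indefinite Hessian"

  if (family == "gaussian") {
    mu <- model_predict(model, th, x)
    sigma <- sqrt(max(mean((y - mu)^2), 1e-12))
    theta <- c(th, sigma = sigma)
    ll <- -neg_log_likelihood(model, theta, x, y, "gaussian")
  } else {
    theta <- th
    ll <- -nll_poisson(model, th, x, y)
  }
  structure(list(model = model, theta = theta, family = family,
                 logLik = ll, k = k, n = n,
                 AICc = if (n - k - 1 > 0) aicc(ll, k, n) else NA_real_,
                 converged = conv, reason = reason,
                 restarts_used = n_restarts, x = x, y = y),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("<model_fit> ", x$model, " (", x$family, "), n = ", x$n,
      ", k = ", x$k, "\n", sep = "")
  if (!is.null(x$theta)) print(round(x$theta, 4))
  cat("logLik = ", format(x$logLik), ", AICc = ", format(x$AICc),
      ", converged = ", x$converged,
      if (!x$converged) paste0(" (", x$reason, ")"), "\n", sep = "")
  invisible(x)
}

#' Rank candidate model fits by AICc
#'
#' Computes dAICc (difference from the minimum AICc over convergent fits)
#' and Akaike weights wAICc, and identifies the parsimonious set
#' (convergent fits with dAICc below the cutoff). When the null model is in
#' the parsimonious set the response is reported as not better explained
#' than by chance.
#'
#' @param fits list of [fit_candidate()] results for one response.
#' @param cutoff dAICc cutoff for the parsimonious set (default 2).
#' @return a `model_ranking`: data frame (model, logLik, k, n, AICc, dAICc,
#'   wAICc, converged, parsimonious) sorted by AICc, with attributes
#'   `best` (model name), `null_in_set` (logical) and `fits`.
#' @export
rank_models <- function(fits, cutoff = 2) {
  if (inherits(fits, "model_fit")) fits <- list(fits)
  tab <- data.frame(
    model = vapply(fits, `[[`, "", "model"),
    logLik = vapply(fits, `[[`, 0, "logLik"),
    k = vapply(fits, function(f) as.numeric(f$k), 0),
    n = vapply(fits, function(f) as.numeric(f$n), 0),
    AICc = vapply(fits, `[[`, 0, "AICc"),
    converged = vapply(fits, `[[`, TRUE, "converged"),
    stringsAsFactors = FALSE)
  conv <- tab$converged & is.finite(tab$AICc)
  if (!any(conv)) stop("no convergent fits to rank")
  tab$dAICc <- NA_real_; tab$wAICc <- NA_real_
  tab$dAICc[conv] <- tab$AICc[conv] - min(tab$AICc[conv])
  w <- exp(-tab$dAICc[conv] / 2)
  tab$wAICc[conv] <- w / sum(w)
  tab$parsimonious <- conv & tab$dAICc <= cutoff
  tab <- tab[order(!conv, tab$AICc),
             c("model", "logLik", "k", "n", "AICc", "dAICc", "wAICc",
               "converged", "parsimonious")]
  rownames(tab) <- NULL
  structure(tab, class = c("model_ranking", "data.frame"),
            best = tab$model[1],
            null_in_set = any(tab$model == "null" & tab$parsimonious),
            fits = setNames(fits, vapply(fits, `[[`, "", "model")))
}

#' Fit and rank the four candidate models for one response
#'
#' Convenience wrapper: fits the null, linear, power-law and four-parameter
#' logistic models with [fit_candidate()] and ranks them with
#' [rank_models()].
#'
#' @inheritParams fit_candidate
#' @param models subset of candidate model names to fit.
#' @param cutoff dAICc cutoff for the parsimonious set.
#' @return a `model_ranking` (see [rank_models()]).
#' @export
fit_cover_models <- function(x, y, family = c("gaussian", "poisson"),
                             models = CANDIDATE_MODELS, cutoff = 2,
                             n_restarts = NULL) {
  family <- match.arg(family)
  fits <- lapply(models, function(m)
    fit_candidate(m, x, y, family = family, n_restarts = n_restarts))
  rank_models(fits, cutoff = cutoff)
}

# Profile nll over x0: re-optimize the remaining logistic parameters with
# the inflection fixed.
profile_nll_x0 <- function(x0, fit) {
  x <- fit$x; y <- fit$y
  pred <- function(p, x0) {
    p["L"] + (p["U"] - p["L"]) / (1 + exp((x0 - x) / p["s"]))
  }
  fn <- if (fit$family == "gaussian") {
    function(p) {
      p <- setNames(p, c("L", "U", "s"))
      if (p["s"] <= 0) return(1e10)
      mu <- pred(p, x0)
      s2 <- max(mean((y - mu)^2), 1e-12)
      0.5 * length(y) * (log(2 * pi * s2) + 1)
    }
  } else {
    function(p) {
      p <- setNames(p, c("L", "U", "s"))
      if (p["s"] <= 0) return(1e10)
      mu <- pred(p, x0)
      if (any(mu <= 0)) return(1e10)
      sum(mu - y * log(mu) + lgamma(y + 1))
    }
  }
  gr <- function(p) {
    th <- c(setNames(p, c("L", "U", "s"))[c("L", "U")], x0 = x0,
            s = unname(p[3]))
    th <- th[c("L", "U", "x0", "s")]
    g4 <- if (fit$family == "gaussian") conc_grad_gaussian("logistic4p", th, x, y)
          else grad_poisson("logistic4p", th, x, y)
    g4[c(1, 2, 4)]
  }
  start <- fit$theta[c("L", "U", "s")]
  ry <- max(diff(range(y)), 1e-6); rx <- max(diff(range(x)), 1e-6)
  opt <- try(optim(start, fn, gr, method = "L-BFGS-B",
                   lower = c(min(y) - 3 * ry, min(y) - 3 * ry, rx * 1e-5),
                   upper = c(max(y) + 3 * ry, max(y) + 3 * ry, 8 * rx),
                   control = list(maxit = 300)), silent = TRUE)
  if (inherits(opt, "try-error")) Inf else opt$value
}

#' Estimate the extinction threshold from a logistic fit
#'
#' The threshold is the fitted inflection point `x0` of the four-parameter
#' logistic: the percent forest cover near which the response changes most
#' rapidly. The confidence interval is obtained by profile likelihood on
#' `x0` (chi-square with 1 df cutoff), falling back to a quadratic (Wald)
#' approximation when profiling fails; bounds are clipped to [0, 100].
#'
#' @param fit a convergent `logistic4p` [fit_candidate()] result.
#' @param level confidence level (default 0.95).
#' @return a `threshold_estimate`: list with `x0`, `ci_low`, `ci_high`,
#'   `level`, `method` (`"profile"` or `"wald"`).
#' @export
estimate_threshold <- function(fit, level = 0.95) {
  if (!inherits(fit, "model_fit") || fit$model != "logistic4p")
    stop("estimate_threshold requires a logistic4p model fit")
  if (!fit$converged)
    stop("estimate_threshold requires a convergent fit")
  x0 <- unname(fit$theta["x0"])
  nll_min <- if (fit$family == "gaussian") {
    conc_nll_gaussian("logistic4p", fit$theta, fit$x, fit$y)
  } else nll_poisson("logistic4p", fit$theta, fit$x, fit$y)
  cutoff <- nll_min + qchisq(level, df = 1) / 2

  f <- function(v) profile_nll_x0(v, fit) - cutoff
  lo_lim <- 0; hi_lim <- 100
  ci <- c(NA_real_, NA_real_); method <- "profile"
  low <- try({
    if (f(lo_lim) <= 0) lo_lim
    else uniroot(f, c(lo_lim, x0), tol = 1e-3)$root
  }, silent = TRUE)
  high <- try({
    if (f(hi_lim) <= 0) hi_lim
    else uniroot(f, c(x0, hi_lim), tol = 1e-3)$root
  }, silent = TRUE)
  if (!inherits(low, "try-error") && !inherits(high, "try-error") &&
      is.finite(low) && is.finite(high)) {
    ci <- c(low, high)
  } else {
    method <- "wald"
    pn <- mean_par_names("logistic4p")
    fn <- if (fit$family == "gaussian") {
      function(th) conc_nll_gaussian("logistic4p", setNames(th, pn), fit$x, fit$y)
    } else {
      function(th) nll_poisson("logistic4p", setNames(th, pn), fit$x, fit$y)
    }
    H <- optimHess(fit$theta[pn], fn)
    se <- sqrt(diag(solve(H)))[which(pn == "x0")]
    z <- qnorm(1 - (1 - level) / 2)
    ci <- c(x0 - z * se, x0 + z * se)
  }
  ci <- pmin(pmax(ci, 0), 100)
  structure(list(x0 = x0, ci_low = min(ci[1], x0), ci_high = max(ci[2], x0),
                 level = level, method = method),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("<threshold_estimate> inflection %.1f%% cover (CI %d%% %.1f-%.1f, %s)\n",
              x$x0, round(100 * x$level), x$ci_low, x$ci_high, x$method))
  invisible(x)
}
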