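# Forest cover vs edge distance: four candidate models (null, cover-only,
# edge-only, cover+edge) on natural-log-transformed predictors, fitted with
# the engine chosen by the earlier stages (GLM when the cover response was
# linear, penalized-spline smoother when it was non-linear, spatial GLS
# when the response was spatially flagged), then ranked by AICc.

#' Choose the engine for the cover-vs-edge comparison
#'
#' Spatially flagged responses always use the spatial engine; otherwise the
#' penalized-spline engine is used when the top-ranked cover-response model
#' was non-linear (power law or logistic), and the GLM engine when it was
#' the null or linear model.
#'
#' @param stage1 a `model_ranking` from the cover-response stage.
#' @param spatial_flag logical: was the response flagged as spatially
#'   correlated?
#' @return list `(engine, reason)` with engine in `c("glm","spline","slm")`.
#' @export
dispatch_engine <- function(stage1, spatial_flag) {
  if (is.null(stage1) || !inherits(stage1, "model_ranking"))
    stop("dispatch_engine needs the stage-1 model ranking")
  if (isTRUE(spatial_flag))
    return(list(engine = "slm", reason = "response spatially flagged"))
  best <- attr(stage1, "best")
  if (best %in% c("power", "logistic4p"))
    return(list(engine = "spline",
                reason = paste0("non-linear model (", best, ") most parsimonious")))
  list(engine = "glm",
       reason = paste0(best, " model most parsimonious, no spatial structure"))
}

#' Penalized cubic-spline smoother
#'
#' Cubic regression-spline basis with a quadratic roughness penalty,
#' fitted by penalized least squares via [mgcv::gam()]. The smoothing
#' parameter is chosen by generalized cross-validation unless given
#' explicitly (`sp`) or implied by a target effective df (`df_target`,
#' matched by root-finding on the smoothing parameter). As the penalty
#' grows the fit collapses onto the straight line (the penalty null
#' space).
#'
#' @param x,y numeric vectors.
#' @param df_target optional target effective degrees of freedom for the
#'   smooth (must satisfy `df_target < n`).
#' @param sp optional fixed smoothing parameter.
#' @param k basis dimension (default `min(10, n - 1)`).
#' @return list with `fit` (the `gam` object), `edf` (total effective df
#'   of the mean structure, intercept included; 2 in the straight-line
#'   limit), `logLik`, `df` (df incl. scale), `sp` and `fitted`.
#' @export
fit_penalized_spline <- function(x, y, df_target = NULL, sp = NULL,
                                 k = NULL) {
  n <- length(y)
  stopifnot(length(x) == n, n >= 5)
  if (!is.null(df_target)) {
    if (df_target >= n) stop("df_target must be smaller than n")
    if (n < df_target + 2) stop("need n >= df_target + 2")
  }
  if (is.null(k)) k <- min(10, n - 1)
  dat <- data.frame(x = x, y = y)
  fit_sp <- function(spv)
    mgcv::gam(y ~ s(x, bs = "cr", k = k), data = dat, method = "GCV.Cp",
              sp = spv)
  if (!is.null(sp)) {
    fit <- fit_sp(sp)
  } else if (!is.null(df_target)) {
    edf_at <- function(lsp) sum(fit_sp(exp(lsp))$edf) - df_target
    lo <- -12; hi <- 16
    if (edf_at(lo) < 0 || edf_at(hi) > 0) {
      fit <- fit_sp(if (edf_at(hi) > 0) exp(hi) else exp(lo))
    } else {
      root <- uniroot(edf_at, c(lo, hi), tol = 1e-4)$root
      fit <- fit_sp(exp(root))
    }
  } else {
    fit <- fit_sp(NULL)
  }
  ll <- logLik(fit)
  list(fit = fit, edf = sum(fit$edf), logLik = as.numeric(ll),
       df = as.numeric(attr(ll, "df")), sp = unname(fit$sp),
       fitted = unname(fitted(fit)))
}

signif_stars <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**",
    ifelse(p <= 0.05, "*", "NS")))
}

# profiled-beta GLS-ML over (phi, tau2, sill) for a fixed design matrix
gls_ml_design <- function(X, y, d, n_restarts = 5) {
  n <- length(y)
  beta_for <- function(S) {
    ch <- chol(S)
    Xi <- backsolve(ch, X, transpose = TRUE)
    yi <- backsolve(ch, y, transpose = TRUE)
    qr.coef(qr(Xi), yi)
  }
  obj <- function(p) {
    phi <- exp(p[1]); tau2 <- exp(p[2]); sill <- exp(p[3])
    S <- exp_covariance(d, phi, tau2, sill)
    ch <- try(chol(S), silent = TRUE)
    if (inherits(ch, "try-error")) return(1e10)
    beta <- beta_for(S)
    mvn_nll(y - as.numeric(X %*% beta), S)
  }
  v <- max(var(y), 1e-8)
  p0 <- c(log(median(d[upper.tri(d)]) / 3), log(v / 2), log(v / 2))
  best <- NULL
  for (i in seq_len(n_restarts)) {
    p <- if (i == 1) p0 else p0 + rnorm(3, 0, 0.8)
    opt <- try(optim(p, obj, method = "Nelder-Mead",
                     control = list(maxit = 1000, reltol = 1e-10)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("spatial covariance optimization failed")
  phi <- exp(best$par[1]); tau2 <- exp(best$par[2]); sill <- exp(best$par[3])
  S <- exp_covariance(d, phi, tau2, sill)
  beta <- beta_for(S)
  Si <- chol2inv(chol(S))
  vb <- solve(t(X) %*% Si %*% X)
  list(beta = setNames(as.numeric(beta), colnames(X)),
       se = sqrt(diag(vb)), logLik = -best$value,
       k = ncol(X) + 3L, n = n, phi = phi, tau2 = tau2, sill = sill,
       converged = best$convergence == 0)
}

as_rank_entry <- function(name, logLik, k, n, converged = TRUE) {
  structure(list(model = name, theta = NULL, family = "gaussian",
                 logLik = logLik, k = k, n = n,
                 AICc = if (n - k - 1 > 0) aicc(logLik, k, n) else NA_real_,
                 converged = converged && n - k - 1 > 0,
                 reason = if (converged) "ok" else "engine fit failed",
                 restarts_used = NA_integer_, x = NULL, y = NULL),
            class = "model_fit")
}

#' Fit and rank the four cover-vs-edge candidate models
#'
#' Natural-log-transforms both predictors (which must be strictly
#' positive), fits the null, cover-only, edge-only and cover+edge models
#' with the requested engine, ranks them by AICc with the dAICc cutoff,
#' and summarizes the best model's coefficient signs and significance
#' (Wald tests for the GLM and spatial engines, the smooth-term
#' approximate test for the spline engine). When the null model is in the
#' parsimonious set, the summary shows a dash for both predictors.
#'
#' @param response a `response_vector` or numeric vector in site order.
#' @param sites a `site_table`.
#' @param engine `"glm"`, `"spline"` or `"slm"` (or the list returned by
#'   [dispatch_engine()]).
#' @param radius buffer radius whose cover is used (default: the smallest;
#'   in the pipeline, the selected scale of effect).
#' @param cutoff dAICc cutoff (default 2).
#' @return a `covariate_model_set`: list with `label`, `engine`, `reason`,
#'   `ranking` (a `model_ranking` over the four candidates), `best` and
#'   `summary` (data frame: predictor, sign, estimate, statistic, p,
#'   stars, shown).
#' @export
build_and_rank <- function(response, sites, engine, radius = NULL,
                           cutoff = 2) {
  reason <- NA_character_
  if (is.list(engine) && !is.null(engine$engine)) {
    reason <- engine$reason; engine <- engine$engine
  }
  engine <- match.arg(engine, c("glm", "spline", "slm"))
  values <- if (inherits(response, "response_vector")) response$values
            else response
  label <- if (inherits(response, "response_vector")) response$label
           else "response"
  if (is.null(radius)) radius <- site_radii(sites)[1]
  cover <- unname(site_cover(sites, radius))
  edge <- sites$edge_dist_m
  if (any(cover <= 0))
    stop("non-positive cover at site(s): ",
         paste(sites$site_id[cover <= 0], collapse = ", "),
         " (log transform undefined)")
  if (any(edge <= 0))
    stop("non-positive edge distance at site(s): ",
         paste(sites$site_id[edge <= 0], collapse = ", "))
  lc <- log(cover); le <- log(edge)
  y <- as.numeric(values)
  n <- length(y)
  cand <- c("null", "cover", "edge", "cover+edge")

  fits <- list(); info <- list()
  if (engine == "glm") {
    forms <- list(null = y ~ 1, cover = y ~ lc, edge = y ~ le,
                  `cover+edge` = y ~ lc + le)
    for (nm in cand) {
      f <- lm(forms[[nm]])
      ll <- logLik(f)
      fits[[nm]] <- as_rank_entry(nm, as.numeric(ll),
                                  as.integer(attr(ll, "df")), n)
      info[[nm]] <- f
    }
  } else if (engine == "spline") {
    dat <- data.frame(y = y, lc = lc, le = le)
    kk <- min(8, n - 2)
    gforms <- list(null = y ~ 1,
                   cover = y ~ s(lc, bs = "cr", k = kk),
                   edge = y ~ s(le, bs = "cr", k = kk),
                   `cover+edge` = y ~ s(lc, bs = "cr", k = kk) +
                     s(le, bs = "cr", k = kk))
    for (nm in cand) {
      f <- mgcv::gam(gforms[[nm]], data = dat, method = "GCV.Cp")
      ll <- logLik(f)
      fits[[nm]] <- as_rank_entry(nm, as.numeric(ll),
                                  as.numeric(attr(ll, "df")), n)
      info[[nm]] <- f
    }
  } else {
    d <- as.matrix(site_distances(sites))
    designs <- list(null = cbind(`(Intercept)` = rep(1, n)),
                    cover = cbind(`(Intercept)` = 1, lc = lc),
                    edge = cbind(`(Intercept)` = 1, le = le),
                    `cover+edge` = cbind(`(Intercept)` = 1, lc = lc, le = le))
    for (nm in cand) {
      g <- gls_ml_design(designs[[nm]], y, d)
      fits[[nm]] <- as_rank_entry(nm, g$logLik, g$k, n, g$converged)
      info[[nm]] <- g
    }
  }
  ranking <- rank_models(fits, cutoff = cutoff)
  best <- attr(ranking, "best")
  null_in_set <- attr(ranking, "null_in_set")

  coef_row <- function(pred, est, stat, p) {
    data.frame(predictor = pred, sign = ifelse(est >= 0, "+", "-"),
               estimate = est, statistic = stat, p = p,
               stars = signif_stars(p), stringsAsFactors = FALSE)
  }
  preds_in <- function(nm) switch(nm, null = character(0),
                                  cover = "cover", edge = "edge",
                                  `cover+edge` = c("cover", "edge"))
  summ <- do.call(rbind, lapply(preds_in(best), function(pred) {
    var <- if (pred == "cover") "lc" else "le"
    if (engine == "glm") {
      ct <- summary(info[[best]])$coefficients
      coef_row(pred, ct[var, 1], ct[var, 3], ct[var, 4])
    } else if (engine == "spline") {
      st <- summary(info[[best]])$s.table
      row <- grep(var, rownames(st))
      tt <- predict(info[[best]], type = "terms")
      trend <- cor(dat[[var]], tt[, grep(var, colnames(tt))])
      data.frame(predictor = pred, sign = ifelse(trend >= 0, "+", "-"),
                 estimate = unname(st[row, "F"]),
                 statistic = unname(st[row, "F"]),
                 p = unname(st[row, "p-value"]),
                 stars = signif_stars(unname(st[row, "p-value"])),
                 stringsAsFactors = FALSE)
    } else {
      g <- info[[best]]
      i <- which(names(g$beta) == var)
      z <- g$beta[i] / g$se[i]
      coef_row(pred, unname(g$beta[i]), unname(z),
               2 * pnorm(-abs(unname(z))))
    }
  }))
  if (is.null(summ))
    summ <- data.frame(predictor = character(0), sign = character(0),
                       estimate = numeric(0), statistic = numeric(0),
                       p = numeric(0), stars = character(0))
  summ$shown <- if (nrow(summ) == 0) character(0)
                else if (null_in_set) "-"
                else paste0(summ$sign, summ$stars)
  structure(list(label = label, engine = engine, reason = reason,
                 ranking = ranking, best = best,
                 null_in_set = null_in_set, summary = summ),
            class = "covariate_model_set")
}
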