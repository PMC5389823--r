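test_that("candidate mean functions evaluate correctly", {
  expect_equal(model_predict("power", c(a = 2, b = 1), 3), 6)
  expect_equal(model_predict("null", c(c = 57), c(1, 50, 99)), rep(57, 3))
  th <- c(L = 3, U = 11, x0 = 30, s = 4)
  # midpoint identity: mu(x0) = (L+U)/2
  expect_equal(model_predict("logistic4p", th, 30), 7)
  # monotone increasing from L to U for s > 0, U > L
  xx <- seq(-100, 160, length.out = 201)
  mu <- model_predict("logistic4p", th, xx)
  expect_true(all(diff(mu) > 0))
  expect_equal(mu[1], 3, tolerance = 1e-6)
  expect_equal(mu[201], 11, tolerance = 1e-6)
  expect_error(model_predict("logistic4p", c(L = 1, U = 2, x0 = 3, s = -1), 5),
               "s must be > 0")
  expect_error(model_predict("power", c(a = 1, b = 1), c(-1, 2)), "x > 0")
})

test_that("negative log-likelihood matches closed forms and density oracles", {
  # zero residuals, sigma = 1, n = 5: nll = 5 * log(2*pi)/2
  x <- 1:5
  expect_equal(
    neg_log_likelihood("null", c(c = 3, sigma = 1), x, rep(3, 5)),
    2.5 * log(2 * pi), tolerance = 1e-12)
  set.seed(51)
  for (rep in 1:5) {
    y <- rnorm(8, 10, 2); s <- runif(1, 0.5, 3)
    got <- neg_log_likelihood("linear", c(b0 = 1, b1 = 2, sigma = s), 1:8, y)
    oracle <- -sum(dnorm(y, 1 + 2 * (1:8), s, log = TRUE))
    expect_equal(got, oracle, tolerance = 1e-10)
  }
  # Poisson with y = mu at every point, via dpois oracle
  mu <- c(2, 5, 9); y <- mu
  got <- neg_log_likelihood("linear", c(b0 = 0, b1 = 1), mu, y,
                            family = "poisson")
  expect_equal(got, -sum(dpois(y, mu, log = TRUE)), tolerance = 1e-10)
  expect_error(
    neg_log_likelihood("linear", c(b0 = -10, b1 = 0), 1:3, 1:3,
                       family = "poisson"), "mu > 0")
  expect_error(neg_log_likelihood("null", c(c = 3, sigma = -1), x, x),
               "sigma")
})

test_that("AICc follows the small-sample formula and its limits", {
  expect_equal(aicc(0, 2, 20), 4 + 12 / 17, tolerance = 1e-12)
  expect_equal(aicc(-10, 3, 1e8), 20 + 6, tolerance = 1e-6)   # AIC limit
  expect_equal(aicc(-7, 0, 10), 14)                           # k = 0
  expect_error(aicc(0, 5, 6), "n > k \\+ 1")
})

test_that("noiseless linear data are recovered to 1e-6", {
  x <- study_covers()
  y <- 2 * x + 1
  f <- fit_candidate("linear", x, y)
  expect_true(f$converged)
  expect_equal(unname(f$theta["b1"]), 2, tolerance = 1e-6)
  expect_equal(unname(f$theta["b0"]), 1, tolerance = 1e-6)
})

test_that("gaussian linear fit matches the OLS closed form", {
  set.seed(52)
  x <- study_covers()
  for (rep in 1:5) {
    y <- 5 + 0.4 * x + rnorm(20, 0, 3)
    f <- fit_candidate("linear", x, y)
    ols <- lm(y ~ x)
    expect_equal(unname(f$theta[c("b0", "b1")]), unname(coef(ols)),
                 tolerance = 1e-6)
    expect_equal(f$logLik, as.numeric(logLik(ols)), tolerance = 1e-6)
  }
})

test_that("power with b = 1 equals a through-origin line in likelihood", {
  x <- study_covers(); y <- 0.7 * x + rnorm(20, 0, 1)
  s <- 1.3
  expect_equal(
    neg_log_likelihood("power", c(a = 0.7, b = 1, sigma = s), x, y),
    neg_log_likelihood("linear", c(b0 = 0, b1 = 0.7, sigma = s), x, y),
    tolerance = 1e-12)
})

test_that("parameter count includes the error parameter", {
  x <- study_covers(); y <- 5 + 0.4 * x + rnorm(20, 0, 2)
  ks <- vapply(c(null = "null", linear = "linear", power = "power",
                 logistic4p = "logistic4p"),
               function(m) fit_candidate(m, x, y)$k, 0)
  expect_equal(unname(ks), c(2, 3, 3, 5))
})

test_that("ranking computes dAICc, weights and the parsimonious set", {
  mk <- function(name, aicc_val) {
    structure(list(model = name, theta = NULL, family = "gaussian",
                   logLik = -1, k = 2, n = 20, AICc = aicc_val,
                   converged = TRUE, reason = "ok", restarts_used = 1L,
                   x = NULL, y = NULL), class = "model_fit")
  }
  rk <- rank_models(list(mk("null", 10), mk("linear", 11.5), mk("power", 14)))
  tab <- as.data.frame(rk)
  expect_equal(tab$dAICc, c(0, 1.5, 4))
  expect_equal(tab$parsimonious, c(TRUE, TRUE, FALSE))
  expect_equal(sum(tab$wAICc), 1, tolerance = 1e-12)
  expect_true(attr(rk, "null_in_set"))
  single <- rank_models(list(mk("linear", 7)))
  expect_equal(as.data.frame(single)$wAICc, 1)
  expect_equal(as.data.frame(single)$dAICc, 0)
  bad <- mk("null", NA); bad$converged <- FALSE
  expect_error(rank_models(list(bad)), "no convergent")
})

test_that("non-convergent fits are excluded from the ranking", {
  x <- study_covers()
  set.seed(53)
  y <- 3 + 0.5 * x + rnorm(20, 0, 1)   # strongly linear
  excluded <- 0
  for (rep in 1:10) {
    yy <- 3 + 0.5 * x + rnorm(20, 0, 1)
    f <- fit_candidate("logistic4p", x, yy)
    if (!f$converged) excluded <- excluded + 1
  }
  # the logistic on linear data is frequently flagged (bounds/Hessian screen)
  expect_gte(excluded, 1)
  # degenerate predictor: non-null models report failure, not an error
  f <- fit_candidate("linear", rep(10, 20), y)
  expect_false(f$converged)
  expect_match(f$reason, "constant")
})

test_that("threshold estimate equals the fitted inflection with a covering CI", {
  set.seed(54)
  x <- study_covers()
  y <- simulate_response(x, "logistic4p", c(L = 10, U = 40, x0 = 29, s = 5),
                         sd = 3)
  f <- fit_candidate("logistic4p", x, y)
  expect_true(f$converged)
  th <- estimate_threshold(f)
  expect_equal(th$x0, unname(f$theta["x0"]))
  expect_lte(th$ci_low, th$x0)
  expect_gte(th$ci_high, th$x0)
  expect_true(th$ci_low >= 0 && th$ci_high <= 100)
  expect_error(estimate_threshold(fit_candidate("linear", x, y)),
               "logistic4p")
})

test_that("poisson likelihood path fits count responses", {
  set.seed(55)
  x <- study_covers()
  y <- simulate_response(x, "linear", c(b0 = 5, b1 = 0.3),
                         family = "poisson")
  rk <- fit_cover_models(x, y, family = "poisson")
  tab <- as.data.frame(rk)
  expect_true(any(tab$converged))
  expect_equal(tab$k[tab$model == "linear"], 2)  # no sigma for poisson
  expect_equal(sum(tab$wAICc[tab$converged]), 1, tolerance = 1e-12)
})
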