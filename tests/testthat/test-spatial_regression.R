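test_that("mean estimate under a fixed known covariance equals closed-form GLS", {
  set.seed(61)
  st <- generate_landscape(generator_config(seed = 61))
  x <- unname(site_cover(st, 1000))
  y <- 10 + 0.3 * x + rnorm(20, 0, 4)
  d <- as.matrix(site_distances(st))
  fc <- list(phi = 20000, tau2 = 4, sill = 9)
  S <- fc$tau2 * diag(20) + fc$sill * exp(-d / fc$phi)
  X <- cbind(1, x)
  oracle <- solve(t(X) %*% solve(S) %*% X, t(X) %*% solve(S) %*% y)
  f <- fit_spatial_linear("linear", x, y, st, fixed_cov = fc)
  expect_equal(unname(f$theta), as.numeric(oracle), tolerance = 1e-4)
  # and the reported logLik is the multivariate-normal log density
  r <- y - X %*% oracle
  ll <- -0.5 * (20 * log(2 * pi) + determinant(S)$modulus[1] +
                  t(r) %*% solve(S) %*% r)
  expect_equal(f$logLik, as.numeric(ll), tolerance = 1e-6)
})

test_that("nugget-only spatial fit coincides with OLS", {
  set.seed(62)
  st <- generate_landscape(generator_config(seed = 62))
  x <- unname(site_cover(st, 1000))
  y <- 4 + 0.5 * x + rnorm(20, 0, 3)
  f <- fit_spatial_linear("linear", x, y, st,
                          fixed_cov = list(phi = 1, tau2 = 4, sill = 0))
  expect_equal(unname(f$theta), unname(coef(lm(y ~ x))), tolerance = 1e-4)
})

test_that("free spatial ML agrees with nlme::gls on linear means", {
  library(nlme)
  set.seed(63)
  st <- generate_landscape(generator_config(seed = 63))
  x <- unname(site_cover(st, 1000))
  d <- as.matrix(site_distances(st))
  S <- 25 * exp(-d / 20000) + 4 * diag(20)
  y <- as.numeric(8 + 0.3 * x + t(chol(S)) %*% rnorm(20))
  f <- fit_spatial_linear("linear", x, y, st, n_restarts = 8)
  dat <- data.frame(y = y, x = x, sx = st$x, sy = st$y)
  g <- nlme::gls(y ~ x, data = dat, method = "ML",
                 correlation = nlme::corExp(form = ~ sx + sy, nugget = TRUE))
  # same likelihood surface: independent implementations should agree closely
  expect_equal(f$logLik, as.numeric(logLik(g)), tolerance = 1e-3)
  expect_equal(unname(f$theta), unname(coef(g)), tolerance = 0.02)
})

test_that("the logistic model is rejected on the spatial path", {
  st <- tiny_sites()
  expect_error(fit_spatial_linear("logistic4p", 1:6, 1:6, st),
               "excluded from spatial linear models")
  set.seed(64)
  stg <- generate_landscape(generator_config(seed = 64))
  x <- unname(site_cover(stg, 1000))
  y <- 5 + 0.2 * x + rnorm(20, 0, 2)
  rk <- fit_spatial_models(x, y, stg)
  expect_equal(sort(as.data.frame(rk)$model), c("linear", "null", "power"))
  expect_equal(sum(as.data.frame(rk)$wAICc, na.rm = TRUE), 1,
               tolerance = 1e-12)
})

test_that("exponential covariance is symmetric positive definite", {
  set.seed(65)
  st <- generate_landscape(generator_config(seed = 65))
  d <- as.matrix(site_distances(st))
  for (rep in 1:10) {
    phi <- runif(1, 500, 80000); tau2 <- runif(1, 0, 10)
    sill <- runif(1, 0.1, 50)
    S <- fragthresh:::exp_covariance(d, phi, tau2, sill)
    expect_equal(S, t(S))
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > 0))
  }
})

test_that("GLS slope SE exceeds the naive OLS SE under positive correlation", {
  # a predictor that follows a spatial gradient plus spatially smooth
  # errors: the classic setting where the naive iid OLS standard error is
  # anti-conservative and the GLS covariance inflates it
  set.seed(66)
  n <- 30
  st <- generate_landscape(generator_config(n_sites = n, seed = 66))
  d <- as.matrix(site_distances(st))
  S <- 25 * exp(-d / 30000) + 1 * diag(n)
  L <- t(chol(S))
  x <- st$x / 1000 + st$y / 2000
  X <- cbind(1, x)
  wider <- 0; n_rep <- 40
  for (rep in 1:n_rep) {
    y <- as.numeric(5 + 0.5 * x + L %*% rnorm(n))
    g <- fragthresh:::gls_ml_design(X, y, d)
    ols <- summary(lm(y ~ x))$coefficients
    if (g$se[2] >= ols[2, 2]) wider <- wider + 1
  }
  expect_gte(wider / n_rep, 0.9)
})

test_that("spatially correlated linear signal beats the null spatial model", {
  set.seed(67)
  st <- generate_landscape(generator_config(seed = 67))
  x <- unname(site_cover(st, 1000))
  d <- as.matrix(site_distances(st))
  S <- 9 * exp(-d / 20000) + 1 * diag(20)
  wins <- 0; n_rep <- 30
  for (rep in 1:n_rep) {
    y <- as.numeric(10 + 0.4 * x + t(chol(S)) %*% rnorm(20))
    rk <- fit_spatial_models(x, y, st, n_restarts = 3)
    tab <- as.data.frame(rk)
    if (tab$AICc[tab$model == "linear"] < tab$AICc[tab$model == "null"])
      wins <- wins + 1
  }
  expect_gte(wins / n_rep, 0.8)
})
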