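test_that("generated landscapes respect the cover gradient and are reproducible", {
  cfg <- generator_config(seed = 42)
  st <- generate_landscape(cfg)
  expect_s3_class(st, "site_table")
  expect_equal(nrow(st), 20)
  for (r in c(500, 1000, 1500, 2000)) {
    cv <- site_cover(st, r)
    expect_true(all(cv >= 3 & cv <= 93))
  }
  # the gradient spans (stratified draw): both tails represented
  expect_lt(min(site_cover(st, 1000)), 10)
  expect_gt(max(site_cover(st, 1000)), 85)
  expect_identical(generate_landscape(cfg), st)
  # minimum intersite separation honoured
  d <- as.matrix(site_distances(st))
  expect_true(all(d[upper.tri(d)] >= 1000))
})

test_that("degenerate landscape configurations behave as documented", {
  st1 <- generate_landscape(generator_config(n_sites = 1, seed = 3))
  expect_equal(nrow(st1), 1)
  expect_equal(length(site_distances(st1)), 0)
  stc <- generate_landscape(generator_config(nested_radius_correlation = 1,
                                             seed = 4))
  expect_equal(site_cover(stc, 500), site_cover(stc, 2000))
  expect_equal(site_cover(stc, 1000), site_cover(stc, 1500))
  expect_error(generator_config(cover_range = c(-5, 93)), "cover_range")
  expect_error(generator_config(cover_range = c(90, 10)), "cover_range")
})

test_that("trait pool reproduces the focal family counts under deterministic rounding", {
  tt <- generate_trait_table(generator_config(seed = 5))
  expect_equal(nrow(tt), 512)
  counts <- table(tt$family)
  expect_equal(unname(counts["Myrtaceae"]), 84)
  expect_equal(unname(counts["Fabaceae"]), 65)
  expect_equal(unname(counts["Rubiaceae"]), 32)
  expect_equal(unname(counts["Sapotaceae"]), 32)
  expect_equal(unname(counts["Lauraceae"]), 25)
})

test_that("degenerate trait probabilities are honoured and validated", {
  cfg <- generator_config(seed = 6, species_pool = list(
    dispersal_probs = c(biotic = 1, abiotic = 0, unknown = 0)))
  tt <- generate_trait_table(cfg)
  expect_true(all(tt$dispersal == "biotic"))
  expect_error(generator_config(species_pool = list(
    dispersal_probs = c(biotic = 0.6, abiotic = 0.6, unknown = 0.1))),
    "sum to 1")
})

test_that("small-seed fraction matches the lognormal CDF at the 1.2 cm cut", {
  cfg <- generator_config(seed = 7, species_pool = list(
    n_species = 10000, seed_known_prob = 1,
    dispersal_probs = c(biotic = 1, abiotic = 0, unknown = 0)))
  tt <- generate_trait_table(cfg)
  frac_small <- mean(tt$seed_class == "small")
  expected <- plnorm(1.2, log(0.8), 0.6)
  expect_lt(abs(frac_small - expected), 3 * sqrt(expected * (1 - expected) / 10000) + 0.005)
})

test_that("noiseless linear richness targets are hit exactly", {
  sites <- tiny_sites()
  cfg <- generator_config(
    n_sites = 6, seed = 8,
    response_spec = list(
      richness = list(form = "linear", params = c(b0 = 10, b1 = 0.5), sd = 0),
      abundance = list(form = "linear", params = c(b0 = 60, b1 = 0.5), sd = 0)),
    species_pool = list(n_species = 100),
    group_effects = list())
  traits <- generate_trait_table(cfg)
  cm <- generate_community(sites, traits, cfg)
  rich <- rowSums(unclass(cm) > 0)
  expect_equal(unname(rich), unname(round(10 + 0.5 * site_cover(sites, 1000))))
  ab <- rowSums(unclass(cm))
  expect_equal(unname(ab), unname(round(60 + 0.5 * site_cover(sites, 1000))))
})

test_that("negative expected responses error before sampling", {
  sites <- tiny_sites()
  cfg <- generator_config(n_sites = 6, seed = 9, response_spec = list(
    richness = list(form = "linear", params = c(b0 = -50, b1 = 0.1), sd = 0),
    abundance = list(form = "linear", params = c(b0 = 60, b1 = 0.5), sd = 0)))
  traits <- generate_trait_table(cfg)
  expect_error(generate_community(sites, traits, cfg), "< 0")
})

test_that("default per-site abundance stays in the surveyed 60-129 range", {
  in_range <- 0; total <- 0
  for (s in 1:40) {
    tabs <- simulate_dataset(generator_config(seed = 1000 + s))
    ab <- rowSums(unclass(tabs$community))
    in_range <- in_range + sum(ab >= 60 & ab <= 129)
    total <- total + length(ab)
  }
  expect_gte(in_range / total, 0.9)
})

test_that("fixed seed gives bit-identical datasets and matrices are valid", {
  cfg <- generator_config(seed = 11)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a, b)
  m <- unclass(a$community)
  expect_true(all(m >= 0))
  expect_true(is.integer(m))
  expect_true(all(colSums(m) > 0))
})

test_that("direct response simulation follows the requested form", {
  x <- study_covers()
  set.seed(2)
  y <- simulate_response(x, "logistic4p", c(L = 5, U = 20, x0 = 30, s = 5),
                         sd = 0)
  expect_equal(y, model_predict("logistic4p",
                                c(L = 5, U = 20, x0 = 30, s = 5), x))
  yp <- simulate_response(x, "null", c(c = 7), family = "poisson")
  expect_true(all(yp >= 0) && all(yp == round(yp)))
  expect_error(simulate_response(x, "null", c(c = -2), family = "poisson"),
               "mu > 0")
})
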