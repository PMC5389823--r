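test_that("seed size classification uses the 1.2 cm frugivore boundary", {
  expect_equal(classify_seed_size(1.2), "small")
  expect_equal(classify_seed_size(1.2001), "large")
  expect_equal(classify_seed_size(NA), "unknown")
  expect_equal(classify_seed_size(c(0.3, 5, NA)),
               c("small", "large", "unknown"))
  expect_error(classify_seed_size(0), "> 0")
  expect_error(classify_seed_size(-1), "> 0")
})

test_that("table validation names the offending rows", {
  df <- as.data.frame(tiny_sites())
  df$cover_500[3] <- 120
  expect_error(as_site_table(df), "cover outside \\[0,100\\].*C")
  df <- as.data.frame(tiny_sites())
  df$site_id[2] <- "A"
  expect_error(as_site_table(df), "duplicate site id.*A")
  df <- as.data.frame(tiny_sites())
  df$edge_dist_m[1] <- 0
  expect_error(as_site_table(df), "edge_dist_m.*A")
  m <- unclass(tiny_community()); m[2, 3] <- -1L
  expect_error(as_community_matrix(m), "negative count.*B")
})

test_that("write-then-read round trip reproduces a random valid dataset", {
  set.seed(101)
  tabs <- simulate_dataset(generator_config(seed = 101))
  dir <- withr::local_tempdir()
  paths <- file.path(dir, c("s.csv", "m.csv", "t.csv"))
  write_tables(tabs, paths[1], paths[2], paths[3])
  back <- load_tables(paths[1], paths[2], paths[3])
  expect_equal(nrow(back$sites), 20)
  expect_equal(site_radii(back$sites), c(500, 1000, 1500, 2000))
  expect_equal(as.data.frame(back$sites), as.data.frame(tabs$sites),
               tolerance = 1e-12)
  expect_identical(unclass(back$community), unclass(tabs$community))
  expect_equal(as.data.frame(back$traits), as.data.frame(tabs$traits),
               tolerance = 1e-12)
})

test_that("species absent from the trait table default to all-unknown", {
  cm <- tiny_community()
  tt <- tiny_traits()[1:4, ]
  out <- cross_reference(tiny_sites(), cm, as_trait_table(tt))
  added <- out$traits[out$traits$species_id %in% c("sp5", "sp6"), ]
  expect_equal(nrow(added), 2)
  expect_true(all(added$family == "unknown"))
  expect_true(all(added$regeneration == "unknown"))
  expect_true(all(added$seed_class == "unknown"))
})

test_that("richness and abundance aggregation matches hand computation", {
  cm <- as_community_matrix(matrix(c(2, 1, 0), 1,
    dimnames = list("s1", c("A", "B", "C"))))
  tt <- as_trait_table(data.frame(species_id = c("A", "B", "C"),
    family = "F1", regeneration = "shade-tolerant", dispersal = "biotic",
    seed_diameter_cm = NA_real_))
  expect_equal(unname(aggregate_response(cm, tt, "all", "richness")$values), 2L)
  expect_equal(unname(aggregate_response(cm, tt, "all", "abundance")$values), 3L)
})

test_that("family subset equals a brute-force filter on random matrices", {
  set.seed(7)
  fams <- c("Myrtaceae", "Fabaceae", "Lauraceae")
  for (rep in 1:10) {
    cm <- random_community(6, 10)
    tt <- as_trait_table(data.frame(
      species_id = colnames(cm),
      family = sample(c(fams, "unknown"), 10, replace = TRUE),
      regeneration = sample(c("shade-tolerant", "shade-intolerant"), 10,
                            replace = TRUE),
      dispersal = sample(c("biotic", "abiotic"), 10, replace = TRUE),
      seed_diameter_cm = NA_real_))
    fam <- sample(intersect(fams, tt$family), 1)
    keep <- tt$species_id[tt$family == fam]
    sub <- unclass(cm)[, keep, drop = FALSE]
    got_r <- aggregate_response(cm, tt, paste0("family=", fam), "richness")
    got_a <- aggregate_response(cm, tt, paste0("family=", fam), "abundance")
    expect_equal(unname(got_r$values), unname(rowSums(sub > 0)))
    expect_equal(unname(got_a$values), unname(rowSums(sub)))
  }
})

test_that("overall abundance is the matrix row sum", {
  cm <- tiny_community()
  got <- aggregate_response(cm, tiny_traits(), "all", "abundance")
  expect_equal(got$values, rowSums(unclass(cm)))
})

test_that("unknown subset labels raise an error listing valid labels", {
  expect_error(
    aggregate_response(tiny_community(), tiny_traits(),
                       "family=Nonexistaceae", "richness"),
    "valid labels.*Fabaceae")
  expect_error(
    aggregate_response(tiny_community(), tiny_traits(), "colour=red"),
    "valid subsets")
})

test_that("aggregation invariants hold on random communities", {
  set.seed(8)
  for (rep in 1:5) {
    tabs <- simulate_dataset(generator_config(n_sites = 8, seed = 300 + rep,
      species_pool = list(n_species = 60)))
    cm <- tabs$community; tt <- tabs$traits
    for (sub in c("all", "regeneration=shade-tolerant", "dispersal=biotic",
                  "seed_class=small")) {
      r <- aggregate_response(cm, tt, sub, "richness")$values
      a <- aggregate_response(cm, tt, sub, "abundance")$values
      expect_true(all(r <= a))
      expect_true(all(r >= 0) && all(a >= 0))
    }
    # seed classes are defined only for biotic-dispersed species
    small <- aggregate_response(cm, tt, "seed_class=small", "abundance")$values
    large <- aggregate_response(cm, tt, "seed_class=large", "abundance")$values
    biotic <- aggregate_response(cm, tt, "dispersal=biotic", "abundance")$values
    expect_true(all(small + large <= biotic))
    # invariance to species column order
    perm <- sample(ncol(cm))
    cm2 <- as_community_matrix(unclass(cm)[, perm])
    expect_equal(aggregate_response(cm2, tt, "all", "richness")$values,
                 aggregate_response(cm, tt, "all", "richness")$values)
  }
})

test_that("response catalogue has 14 trait+overall and 24 total entries", {
  expect_equal(nrow(response_catalogue(NULL)), 14)
  full <- response_catalogue()
  expect_equal(nrow(full), 24)
  expect_equal(sum(full$group_type == "family"), 10)
  expect_equal(anyDuplicated(full$label), 0)
})
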