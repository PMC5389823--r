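# fixtures built in code: a minimal hand-written dataset and generator shortcuts

tiny_sites <- function() {
  as_site_table(data.frame(
    site_id = c("A", "B", "C", "D", "E", "F"),
    x = c(0, 10000, 20000, 0, 10000, 20000),
    y = c(0, 0, 0, 15000, 15000, 15000),
    cover_500 = c(5, 20, 35, 50, 70, 90),
    cover_1000 = c(8, 22, 33, 55, 68, 88),
    cover_1500 = c(10, 25, 30, 52, 66, 85),
    cover_2000 = c(12, 24, 31, 50, 65, 83),
    edge_dist_m = c(40, 60, 80, 120, 150, 200)))
}

tiny_traits <- function() {
  as_trait_table(data.frame(
    species_id = paste0("sp", 1:6),
    family = c("Myrtaceae", "Myrtaceae", "Fabaceae", "Lauraceae",
               "Rubiaceae", "unknown"),
    regeneration = c("shade-tolerant", "shade-intolerant", "shade-tolerant",
                     "shade-tolerant", "unknown", "shade-intolerant"),
    dispersal = c("biotic", "biotic", "abiotic", "biotic", "biotic",
                  "unknown"),
    seed_diameter_cm = c(0.5, 2.0, NA, 1.2, NA, NA)))
}

tiny_community <- function() {
  m <- matrix(c(2, 1, 0, 3, 0, 1,
                0, 4, 1, 0, 2, 0,
                1, 0, 0, 2, 1, 1,
                5, 2, 3, 0, 0, 0,
                0, 0, 2, 1, 4, 2,
                3, 1, 0, 0, 1, 0), nrow = 6, byrow = TRUE,
              dimnames = list(c("A", "B", "C", "D", "E", "F"),
                              paste0("sp", 1:6)))
  as_community_matrix(m)
}

# random valid community matrix for oracle-based properties
random_community <- function(n_sites, n_species, lambda = 2) {
  m <- matrix(rpois(n_sites * n_species, lambda), n_sites, n_species,
              dimnames = list(sprintf("s%02d", seq_len(n_sites)),
                              sprintf("sp%02d", seq_len(n_species))))
  as_community_matrix(m)
}

study_covers <- function(n = 20) seq(3, 93, length.out = n)
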