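#' fragthresh: extinction thresholds along landscape forest-cover gradients
#'
#' Analyses how tree community attributes respond to the amount of forest
#' cover measured in multi-radius landscape buffers around survey sites:
#' scale-of-effect selection, spatial-dependence screening, four-model
#' maximum-likelihood selection with AICc, logistic extinction-threshold
#' estimation, spatial linear models, a cover-versus-edge covariate
#' comparison and community ordination, plus a synthetic-data generator
#' emulating fragmented tropical-forest surveys.
#'
#' @keywords internal
#' @aliases fragthresh-package
"_PACKAGE"

#' @importFrom stats cor dist lm coef logLik optim optimHess
#'   quantile rnorm runif rpois rmultinom qchisq qnorm pnorm uniroot sd var
#'   median predict fitted setNames rlnorm
#' @importFrom utils read.csv write.csv
#' @importFrom mgcv gam s
NULL

# ---- site table -------------------------------------------------------------

#' Construct and validate a site table
#'
#' A site table holds one row per survey site: an identifier, projected
#' x/y coordinates in metres, percent forest cover within each of a set of
#' circular landscape buffers (columns named `cover_<radius>`, radius in
#' metres), and the mean linear distance from the survey plots to the
#' nearest forest edge (`edge_dist_m`, metres).
#'
#' @param df data frame with columns `site_id`, `x`, `y`, one or more
#'   `cover_<radius>` columns and `edge_dist_m`.
#' @return the validated data frame with class `site_table`.
#' @examples
#' st <- as_site_table(data.frame(
#'   site_id = c("A", "B"), x = c(0, 1000), y = c(0, 0),
#'   cover_500 = c(10, 80), cover_1000 = c(12, 75), edge_dist_m = c(50, 200)))
#' site_radii(st)
#' @export
as_site_table <- function(df) {
  df <- as.data.frame(df)
  needed <- c("site_id", "x", "y", "edge_dist_m")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0)
    stop("site table is missing column(s): ", paste(miss, collapse = ", "))
  cov_cols <- grep("^cover_[0-9]+$", names(df), value = TRUE)
  if (length(cov_cols) == 0)
    stop("site table needs at least one cover_<radius> column")
  df$site_id <- as.character(df$site_id)
  if (anyDuplicated(df$site_id))
    stop("duplicate site id(s): ",
         paste(unique(df$site_id[duplicated(df$site_id)]), collapse = ", "))
  for (cc in cov_cols) {
    bad <- which(!is.finite(df[[cc]]) | df[[cc]] < 0 | df[[cc]] > 100)
    if (length(bad) > 0)
      stop("cover outside [0,100] in column ", cc, " for site(s): ",
           paste(df$site_id[bad], collapse = ", "))
  }
  bad <- which(!is.finite(df$edge_dist_m) | df$edge_dist_m <= 0)
  if (length(bad) > 0)
    stop("edge_dist_m must be > 0; offending site(s): ",
         paste(df$site_id[bad], collapse = ", "))
  if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
    stop("site coordinates must be finite")
  class(df) <- c("site_table", "data.frame")
  df
}

#' Buffer radii available in a site table
#'
#' @param sites a `site_table`.
#' @return sorted numeric vector of radii (m) parsed from the
#'   `cover_<radius>` column names.
#' @export
site_radii <- function(sites) {
  cols <- grep("^cover_[0-9]+$", names(sites), value = TRUE)
  sort(as.numeric(sub("^cover_", "", cols)))
}

#' Percent forest cover at one radius
#'
#' @param sites a `site_table`.
#' @param radius buffer radius in metres; must match a `cover_<radius>` column.
#' @return numeric vector of percent cover, named by site id.
#' @export
site_cover <- function(sites, radius) {
  col <- paste0("cover_", format(radius, scientific = FALSE, trim = TRUE))
  if (!col %in% names(sites))
    stop("no cover column for radius ", radius, "; available: ",
         paste(site_radii(sites), collapse = ", "))
  setNames(sites[[col]], sites$site_id)
}

#' Pairwise Euclidean distances between sites (metres)
#'
#' @param sites a `site_table`.
#' @return a `dist` object over sites, in site-table order.
#' @export
site_distances <- function(sites) {
  d <- dist(cbind(sites$x, sites$y))
  attr(d, "Labels") <- sites$site_id
  d
}

# ---- community matrix -------------------------------------------------------

#' Construct and validate a site-by-species community matrix
#'
#' Counts of individuals per site (rows) and species (columns). Row sums
#' are the per-site abundance (total individuals recorded at the site).
#'
#' @param m numeric matrix or data frame of non-negative integer counts
#'   with row names = site ids and column names = species ids.
#' @return integer matrix with class `community_matrix`.
#' @export
as_community_matrix <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("community matrix needs site row names and species column names")
  if (any(!is.finite(m)))
    stop("community matrix contains non-finite values")
  if (any(m < 0)) {
    bad <- which(rowSums(m < 0) > 0)
    stop("negative count(s) in row(s): ",
         paste(rownames(m)[bad], collapse = ", "))
  }
  if (max(abs(m - round(m))) > 1e-8)
    stop("community matrix counts must be integers")
  storage.mode(m) <- "integer"
  class(m) <- c("community_matrix", class(m))
  m
}

# ---- trait table ------------------------------------------------------------

REGEN_LEVELS    <- c("shade-tolerant", "shade-intolerant", "unknown")
DISPERSAL_LEVELS <- c("biotic", "abiotic", "unknown")
SEED_LEVELS     <- c("small", "large", "unknown")

#' Classify seed size from seed diameter
#'
#' Seeds with diameter at most 1.2 cm are "small" (swallowed by small-bodied
#' frugivorous birds); larger seeds are "large" (handled by large-bodied
#' birds and mammals). Missing diameters give "unknown".
#'
#' @param diameter seed diameter in cm; may contain `NA`.
#' @return character vector in `c("small", "large", "unknown")`.
#' @examples
#' classify_seed_size(c(0.5, 1.2, 1.3, NA))
#' @export
classify_seed_size <- function(diameter) {
  if (any(!is.na(diameter) & diameter <= 0))
    stop("seed diameter must be > 0 cm (or missing)")
  out <- rep("unknown", length(diameter))
  out[!is.na(diameter) & diameter <= 1.2] <- "small"
  out[!is.na(diameter) & diameter > 1.2]  <- "large"
  out
}

#' Construct and validate a species trait table
#'
#' One row per species with its family, regeneration strategy
#' (shade-tolerant vs shade-intolerant), dispersal mode (biotic = vertebrate
#' dispersed, abiotic = wind/autochory) and seed diameter (cm). The seed
#' size class is derived from the diameter with [classify_seed_size()]
#' unless a consistent `seed_class` column is supplied.
#'
#' @param df data frame with columns `species_id`, `family`, `regeneration`,
#'   `dispersal`, `seed_diameter_cm` (and optionally `seed_class`).
#' @return validated data frame with class `trait_table`.
#' @export
as_trait_table <- function(df) {
  df <- as.data.frame(df)
  needed <- c("species_id", "family", "regeneration", "dispersal",
              "seed_diameter_cm")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0)
    stop("trait table is missing column(s): ", paste(miss, collapse = ", "))
  df$species_id <- as.character(df$species_id)
  if (anyDuplicated(df$species_id))
    stop("duplicate species id(s): ",
         paste(unique(df$species_id[duplicated(df$species_id)]), collapse = ", "))
  df$family <- as.character(df$family)
  df$family[is.na(df$family) | df$family == ""] <- "unknown"
  for (col in c("regeneration", "dispersal")) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][is.na(df[[col]]) | df[[col]] == ""] <- "unknown"
  }
  if (!all(df$regeneration %in% REGEN_LEVELS))
    stop("regeneration values must be one of: ",
         paste(REGEN_LEVELS, collapse = ", "))
  if (!all(df$dispersal %in% DISPERSAL_LEVELS))
    stop("dispersal values must be one of: ",
         paste(DISPERSAL_LEVELS, collapse = ", "))
  derived <- classify_seed_size(df$seed_diameter_cm)
  if ("seed_class" %in% names(df)) {
    df$seed_class <- as.character(df$seed_class)
    df$seed_class[is.na(df$seed_class) | df$seed_class == ""] <- "unknown"
    if (!all(df$seed_class %in% SEED_LEVELS))
      stop("seed_class values must be one of: ", paste(SEED_LEVELS, collapse = ", "))
    has_d <- !is.na(df$seed_diameter_cm)
    if (any(df$seed_class[has_d] != derived[has_d]))
      stop("seed_class inconsistent with seed_diameter_cm for species: ",
           paste(df$species_id[has_d & df$seed_class != derived], collapse = ", "))
  } else {
    df$seed_class <- derived
  }
  class(df) <- c("trait_table", "data.frame")
  df
}

unknown_traits <- function(species_ids) {
  as_trait_table(data.frame(
    species_id = species_ids, family = "unknown",
    regeneration = "unknown", dispersal = "unknown",
    seed_diameter_cm = NA_real_, stringsAsFactors = FALSE))
}

# ---- I/O --------------------------------------------------------------------

#' Read the three analysis tables from CSV files
#'
#' Reads and cross-references the site table, the site-by-species community
#' matrix (first column = site id, remaining columns = species counts) and
#' the species trait table. Species present in the matrix but absent from
#' the trait table are retained with all traits set to "unknown"; matrix
#' rows are reordered to match the site table.
#'
#' @param site_path,matrix_path,trait_path CSV file paths.
#' @return list with elements `sites` ([as_site_table()]),
#'   `community` ([as_community_matrix()]) and `traits` ([as_trait_table()]).
#' @export
load_tables <- function(site_path, matrix_path, trait_path) {
  sites <- as_site_table(read.csv(site_path, stringsAsFactors = FALSE))
  mdf <- read.csv(matrix_path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(mdf[, -1, drop = FALSE])
  rownames(m) <- as.character(mdf[[1]])
  community <- as_community_matrix(m)
  traits <- as_trait_table(read.csv(trait_path, stringsAsFactors = FALSE))
  cross_reference(sites, community, traits)
}

#' Cross-reference site, community and trait objects
#'
#' @param sites a `site_table`; @param community a `community_matrix`;
#' @param traits a `trait_table`.
#' @return list `(sites, community, traits)` with matrix rows aligned to the
#'   site table and every matrix species present in the trait table.
#' @export
cross_reference <- function(sites, community, traits) {
  if (!setequal(rownames(community), sites$site_id))
    stop("community matrix sites do not match site table ids")
  community <- community[sites$site_id, , drop = FALSE]
  class(community) <- c("community_matrix", "matrix", "array")
  missing_sp <- setdiff(colnames(community), traits$species_id)
  if (length(missing_sp) > 0) {
    traits <- rbind(as.data.frame(traits), as.data.frame(unknown_traits(missing_sp)))
    traits <- as_trait_table(traits)
  }
  list(sites = sites, community = community, traits = traits)
}

#' Write the three analysis tables to CSV files
#'
#' Inverse of [load_tables()]; numbers are written with full precision so a
#' write-then-read round trip reproduces the objects.
#'
#' @param tables list `(sites, community, traits)`.
#' @param site_path,matrix_path,trait_path output CSV paths.
#' @return invisibly, the paths written.
#' @export
write_tables <- function(tables, site_path, matrix_path, trait_path) {
  sdf <- as.data.frame(tables$sites)
  num <- vapply(sdf, is.numeric, TRUE)
  sdf[num] <- lapply(sdf[num], function(v)
    format(v, digits = 17, trim = TRUE, scientific = FALSE))
  write.csv(sdf, site_path, row.names = FALSE, quote = TRUE)
  m <- tables$community
  mdf <- data.frame(site_id = rownames(m), as.data.frame(unclass(m)),
                    check.names = FALSE)
  write.csv(mdf, matrix_path, row.names = FALSE, quote = TRUE)
  tdf <- as.data.frame(tables$traits)
  tdf$seed_diameter_cm <- ifelse(is.na(tdf$seed_diameter_cm), "",
                                 format(tdf$seed_diameter_cm, digits = 17,
                                        trim = TRUE, scientific = FALSE))
  write.csv(tdf, trait_path, row.names = FALSE, quote = TRUE)
  invisible(c(site_path, matrix_path, trait_path))
}

# ---- response aggregation ---------------------------------------------------

valid_subsets <- function(traits) {
  fams <- sort(setdiff(unique(traits$family), "unknown"))
  c("all",
    paste0("family=", fams),
    paste0("regeneration=", setdiff(REGEN_LEVELS, "unknown")),
    paste0("dispersal=", setdiff(DISPERSAL_LEVELS, "unknown")),
    paste0("seed_class=", setdiff(SEED_LEVELS, "unknown")))
}

subset_species <- function(traits, subset) {
  if (identical(subset, "all")) return(traits$species_id)
  parts <- strsplit(subset, "=", fixed = TRUE)[[1]]
  if (length(parts) != 2 ||
      !parts[1] %in% c("family", "regeneration", "dispersal", "seed_class"))
    stop("unknown subset '", subset, "'; valid subsets: ",
         paste(valid_subsets(traits), collapse = ", "))
  col <- parts[1]; level <- parts[2]
  ok_levels <- sort(setdiff(unique(traits[[col]]), "unknown"))
  if (!level %in% ok_levels)
    stop("unknown ", col, " label '", level, "'; valid labels: ",
         paste(ok_levels, collapse = ", "))
  # species with "unknown" for the subsetting trait never enter the subset
  traits$species_id[traits[[col]] == level]
}

#' Aggregate a community response across a species subset
#'
#' Computes per-site species richness (number of species with at least one
#' individual) or abundance (total individuals) for the whole community, a
#' family, or a functional-trait group. Species whose value for the
#' subsetting trait is "unknown" are excluded from that subset but retained
#' in the overall ("all") responses.
#'
#' @param community a `community_matrix`.
#' @param traits a `trait_table` covering the matrix species.
#' @param subset `"all"`, `"family=<name>"`, `"regeneration=<level>"`,
#'   `"dispersal=<level>"` or `"seed_class=<level>"`.
#' @param kind `"richness"` or `"abundance"`.
#' @return a `response_vector`: list with `label`, `kind`, `subset` and
#'   integer `values` named by site id.
#' @examples
#' cm <- as_community_matrix(matrix(c(2, 1, 0, 0, 3, 1), nrow = 2,
#'   dimnames = list(c("s1", "s2"), c("spA", "spB", "spC"))))
#' tt <- as_trait_table(data.frame(species_id = c("spA", "spB", "spC"),
#'   family = "Myrtaceae", regeneration = "shade-tolerant",
#'   dispersal = "biotic", seed_diameter_cm = 1))
#' aggregate_response(cm, tt, "all", "richness")$values
#' @export
aggregate_response <- function(community, traits,
                               subset = "all",
                               kind = c("richness", "abundance")) {
  kind <- match.arg(kind)
  sp <- intersect(colnames(community), subset_species(traits, subset))
  sub <- community[, sp, drop = FALSE]
  values <- if (kind == "richness") as.integer(rowSums(sub > 0))
            else as.integer(rowSums(sub))
  label <- if (identical(subset, "all")) paste0("overall-", kind)
           else paste0(sub("^[a-z_]+=", "", subset), "-", kind)
  structure(list(label = label, kind = kind, subset = subset,
                 values = setNames(values, rownames(community))),
            class = "response_vector")
}

#' @export
print.response_vector <- function(x, ...) {
  cat("<response_vector> ", x$label, " (", x$kind, ", ",
      length(x$values), " sites)\n", sep = "")
  print(x$values)
  invisible(x)
}

#' Standard catalogue of community responses
#'
#' The default analysis catalogue: richness and abundance for the overall
#' community and for each functional-trait group (2 regeneration x 2
#' dispersal x 2 seed-size levels: 14 responses), plus, optionally, for a
#' set of focal families (10 more with the default five families).
#'
#' @param families character vector of family names to include, or `NULL`.
#' @return data frame with columns `subset`, `kind`, `label`,
#'   `group_type` (`"overall"`, `"trait"` or `"family"`).
#' @export
response_catalogue <- function(families = c("Myrtaceae", "Fabaceae",
                                            "Rubiaceae", "Sapotaceae",
                                            "Lauraceae")) {
  subsets <- c("all",
               paste0("regeneration=", c("shade-tolerant", "shade-intolerant")),
               paste0("dispersal=", c("biotic", "abiotic")),
               paste0("seed_class=", c("small", "large")))
  type <- c("overall", rep("trait", 6))
  if (length(families) > 0) {
    subsets <- c(subsets, paste0("family=", families))
    type <- c(type, rep("family", length(families)))
  }
  out <- expand.grid(kind = c("richness", "abundance"), subset = subsets,
                     stringsAsFactors = FALSE)[, c("subset", "kind")]
  out$group_type <- rep(type, each = 2)
  out$label <- ifelse(out$subset == "all", paste0("overall-", out$kind),
                      paste0(sub("^[a-z_]+=", "", out$subset), "-", out$kind))
  out
}
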