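# End-to-end orchestration: scale selection -> spatial screening ->
# per-response four-model selection (spatial path for flagged responses)
# -> threshold extraction -> cover-vs-edge covariate comparison ->
# ordination, with publication-style report tables.

#' Configuration for a full pipeline run
#'
#' @param tables optional pre-built list `(sites, community, traits)`.
#' @param paths optional list `(site, matrix, trait)` of CSV paths for
#'   [load_tables()].
#' @param generator a [generator_config()] used when neither `tables` nor
#'   `paths` is given.
#' @param families focal families for family-level responses (the trait
#'   and overall responses are always included).
#' @param alpha envelope level for spatial screening.
#' @param n_sim Monte-Carlo simulations for the envelope (default 1000).
#' @param cutoff dAICc cutoff for parsimonious sets (default 2).
#' @param error_family `"gaussian"` or `"poisson"` likelihood for the
#'   cover-response models.
#' @param screen_families also screen family responses for spatial
#'   correlation (default `FALSE`: only the 14 overall + trait responses
#'   are screened; family responses take the non-spatial path).
#' @param detrend_segments segments for ordination detrending.
#' @param n_restarts optimizer restarts passed to the fitters.
#' @param seed integer seed controlling every stochastic stage.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(tables = NULL, paths = NULL,
                            generator = generator_config(),
                            families = c("Myrtaceae", "Fabaceae",
                                         "Rubiaceae", "Sapotaceae",
                                         "Lauraceae"),
                            alpha = 0.05, n_sim = 1000, cutoff = 2,
                            error_family = "gaussian",
                            screen_families = FALSE,
                            detrend_segments = 26,
                            n_restarts = NULL, seed = 1) {
  if (cutoff <= 0) stop("dAICc cutoff must be > 0")
  structure(list(tables = tables, paths = paths, generator = generator,
                 families = families, alpha = alpha, n_sim = n_sim,
                 cutoff = cutoff, error_family = error_family,
                 screen_families = screen_families,
                 detrend_segments = detrend_segments,
                 n_restarts = n_restarts, seed = as.integer(seed)),
            class = "analysis_config")
}

stage_try <- function(stage, response, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "'",
         if (!is.na(response)) paste0(" (response ", response, ")"),
         " failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full landscape-threshold analysis
#'
#' Executes, in order: response aggregation over the catalogue (overall +
#' trait groups + families); scale-of-effect selection (Spearman over all
#' buffer radii, majority winner chosen); Monte-Carlo semivariogram
#' screening of the overall + trait responses; per-response model
#' selection (three spatial candidates for flagged responses, the four
#' maximum-likelihood candidates otherwise); extinction-threshold
#' estimation wherever the logistic model is in the parsimonious set;
#' the cover-vs-edge four-model comparison with the engine dispatched per
#' response; and detrended correspondence analysis of the community
#' matrix. Fully reproducible: the same seed gives an identical bundle.
#'
#' @param config an [analysis_config()].
#' @return a `fragthresh_report` bundle: list with `data`, `responses`,
#'   `scale`, `spatial`, `model_selection` (long data frame), `rankings`,
#'   `thresholds`, `covariates`, `covariate_table`, `ordination`,
#'   `best_model_summary` and `config`.
#' @export
run_pipeline <- function(config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  set.seed(config$seed)
  tables <- stage_try("load", NA, {
    if (!is.null(config$tables)) config$tables
    else if (!is.null(config$paths))
      load_tables(config$paths$site, config$paths$matrix, config$paths$trait)
    else simulate_dataset(config$generator)
  })
  sites <- tables$sites; community <- tables$community
  traits <- tables$traits

  cat_df <- response_catalogue(config$families)
  responses <- stage_try("aggregate", NA, lapply(seq_len(nrow(cat_df)),
    function(i) aggregate_response(community, traits,
                                   cat_df$subset[i], cat_df$kind[i])))
  names(responses) <- cat_df$label

  scale <- stage_try("scale_selection", NA,
                     scale_summary(responses, sites))
  radius <- scale$chosen_radius
  x <- unname(site_cover(sites, radius))

  screen_idx <- if (config$screen_families) seq_len(nrow(cat_df))
                else which(cat_df$group_type %in% c("overall", "trait"))
  spatial <- setNames(vector("list", nrow(cat_df)), cat_df$label)
  for (i in screen_idx) {
    spatial[[i]] <- stage_try("spatial_screening", cat_df$label[i],
      mc_envelope_test(sites, responses[[i]], n_sim = config$n_sim,
                       alpha = config$alpha))
  }
  flagged <- vapply(spatial, function(s)
    if (is.null(s)) FALSE else isTRUE(is_flagged(s)), TRUE)

  rankings <- setNames(vector("list", nrow(cat_df)), cat_df$label)
  for (i in seq_len(nrow(cat_df))) {
    lab <- cat_df$label[i]
    rankings[[i]] <- stage_try("model_selection", lab, {
      if (flagged[i])
        fit_spatial_models(x, responses[[i]]$values, sites,
                           cutoff = config$cutoff)
      else
        fit_cover_models(x, responses[[i]]$values,
                         family = config$error_family,
                         cutoff = config$cutoff,
                         n_restarts = config$n_restarts)
    })
  }
  model_selection <- do.call(rbind, lapply(seq_len(nrow(cat_df)), function(i) {
    tab <- as.data.frame(rankings[[i]])
    cbind(response = cat_df$label[i],
          path = if (flagged[i]) "slm" else "ml", tab)
  }))
  rownames(model_selection) <- NULL

  thresholds <- list()
  for (i in seq_len(nrow(cat_df))) {
    rk <- rankings[[i]]
    tab <- as.data.frame(rk)
    if (flagged[i] || !any(tab$model == "logistic4p" & tab$parsimonious))
      next
    fit <- attr(rk, "fits")[["logistic4p"]]
    th <- stage_try("threshold", cat_df$label[i], estimate_threshold(fit))
    thresholds[[cat_df$label[i]]] <- th
  }
  threshold_table <- if (length(thresholds) == 0) {
    data.frame(response = character(0), x0 = numeric(0),
               ci_low = numeric(0), ci_high = numeric(0),
               method = character(0))
  } else {
    data.frame(response = names(thresholds),
               x0 = vapply(thresholds, `[[`, 0, "x0"),
               ci_low = vapply(thresholds, `[[`, 0, "ci_low"),
               ci_high = vapply(thresholds, `[[`, 0, "ci_high"),
               method = vapply(thresholds, `[[`, "", "method"),
               row.names = NULL)
  }

  covariates <- setNames(vector("list", nrow(cat_df)), cat_df$label)
  for (i in seq_len(nrow(cat_df))) {
    lab <- cat_df$label[i]
    covariates[[i]] <- stage_try("covariates", lab, {
      eng <- dispatch_engine(rankings[[i]], flagged[i])
      build_and_rank(responses[[i]], sites, eng, radius = radius,
                     cutoff = config$cutoff)
    })
  }
  covariate_table <- do.call(rbind, lapply(covariates, function(cv) {
    tab <- as.data.frame(cv$ranking)
    cbind(response = cv$label, engine = cv$engine, tab)
  }))
  rownames(covariate_table) <- NULL

  ordination <- stage_try("ordination", NA, {
    ca <- suppressWarnings(correspondence_analysis(community, n_axes = 4))
    suppressWarnings(detrend_axis(ca, n_segments = config$detrend_segments))
  })

  bundle <- structure(list(
    data = tables, catalogue = cat_df, responses = responses,
    scale = scale, chosen_radius = radius,
    spatial = spatial, flagged = flagged,
    rankings = rankings, model_selection = model_selection,
    thresholds = thresholds, threshold_table = threshold_table,
    covariates = covariates, covariate_table = covariate_table,
    ordination = ordination, config = config),
    class = "fragthresh_report")
  bundle$best_model_summary <- summarize_best_models(bundle)
  bundle
}

#' Table-1/2-style summary of the best covariate models
#'
#' One row per response: the engine used, and per predictor (edge
#' distance, cover amount) the coefficient sign with significance stars, a
#' dash when the null model was in the parsimonious set, `NS` for a
#' retained but non-significant term, and blank when the predictor is not
#' in the best model.
#'
#' @param bundle a `fragthresh_report` from [run_pipeline()].
#' @return data frame (response, kind, engine, best_model, edge_distance,
#'   cover_amount).
#' @export
summarize_best_models <- function(bundle) {
  stopifnot(inherits(bundle, "fragthresh_report"))
  rows <- lapply(bundle$covariates, function(cv) {
    cell <- function(pred) {
      if (cv$null_in_set) return("-")
      s <- cv$summary[cv$summary$predictor == pred, , drop = FALSE]
      if (nrow(s) == 0) return("")
      if (s$stars == "NS") "NS" else paste0(s$sign, s$stars)
    }
    data.frame(response = cv$label, engine = cv$engine,
               best_model = cv$best,
               edge_distance = cell("edge"),
               cover_amount = cell("cover"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$kind <- bundle$catalogue$kind[match(out$response,
                                          bundle$catalogue$label)]
  rownames(out) <- NULL
  out[, c("response", "kind", "engine", "best_model",
          "edge_distance", "cover_amount")]
}

#' @export
print.fragthresh_report <- function(x, ...) {
  cat("<fragthresh_report>\n")
  cat("  sites:", nrow(x$data$sites),
      " species observed:", ncol(x$data$community), "\n")
  cat("  responses analysed:", length(x$responses),
      " | spatially flagged:", sum(x$flagged), "\n")
  cat("  scale of effect:", x$chosen_radius, "m\n")
  cat("  thresholds estimated:", nrow(x$threshold_table), "\n")
  cat("  DCA axis 1 variance: ",
      sprintf("%.1f%%", 100 * x$ordination$variance_fraction[1]), "\n",
      sep = "")
  invisible(x)
}

#' Write a report bundle to CSV files with a JSON sidecar
#'
#' Writes the publication-style tables (scale selection, spatial screening,
#' model-selection rankings, thresholds, covariate rankings, best-model
#' summary, ordination scores and eigenvalues) as CSV, plus `report.json`
#' holding the fitted parameters, flags and the seed for machine
#' comparison. Output contains no timestamps, so runs with the same seed
#' produce byte-identical files.
#'
#' @param bundle a `fragthresh_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the files written.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "fragthresh_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wcsv <- function(df, name) {
    path <- file.path(dir, name)
    write.csv(format(as.data.frame(df), digits = 12, trim = TRUE,
                     scientific = FALSE),
              path, row.names = FALSE, quote = TRUE)
    path
  }
  files <- c(
    wcsv(bundle$scale$per_response, "scale_selection.csv"),
    wcsv(bundle$scale$winning_fraction, "scale_winning_fraction.csv"),
    wcsv(data.frame(response = names(bundle$flagged),
                    screened = !vapply(bundle$spatial, is.null, TRUE),
                    flagged = unname(bundle$flagged)),
         "spatial_screening.csv"),
    wcsv(bundle$model_selection, "model_selection.csv"),
    wcsv(bundle$threshold_table, "thresholds.csv"),
    wcsv(bundle$covariate_table, "covariate_ranking.csv"),
    wcsv(bundle$best_model_summary, "best_model_summary.csv"),
    wcsv(data.frame(axis = seq_along(bundle$ordination$eigenvalues),
                    eigenvalue = bundle$ordination$eigenvalues,
                    variance_fraction = bundle$ordination$variance_fraction),
         "ordination_eigenvalues.csv"),
    wcsv(data.frame(site_id = rownames(bundle$ordination$site_scores),
                    bundle$ordination$site_scores),
         "ordination_site_scores.csv"))
  sidecar <- list(
    seed = bundle$config$seed,
    chosen_radius_m = bundle$chosen_radius,
    n_responses = length(bundle$responses),
    n_flagged = sum(bundle$flagged),
    thresholds = bundle$threshold_table,
    fitted_parameters = lapply(bundle$rankings, function(rk) {
      lapply(attr(rk, "fits"), function(f)
        list(model = f$model, converged = f$converged,
             theta = as.list(f$theta), logLik = f$logLik, AICc = f$AICc))
    }),
    ordination_axis1_fraction = bundle$ordination$variance_fraction[1])
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(files, json_path))
}
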