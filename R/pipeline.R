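#' Configure an end-to-end pipeline run
#'
#' Exactly one data source must be active: `params` (simulate plant records
#' from the generative model) or `input_path` (read an existing plant-record
#' CSV). All stage seeds are derived deterministically from the master seed
#' (data = seed + 1, mortality = seed + 2, coefficient draws = seed + 100 +
#' fit index in sorted key order), so partial reruns agree with full runs.
#'
#' @param mode Design mode, see [design_config()].
#' @param params A [true_params()] object, for simulation runs.
#' @param input_path Path to a plant-record CSV, for data runs.
#' @param S Monte-Carlo draws per fitted model (>= 1000; default 100,000).
#' @param seed Master integer seed.
#' @param out_dir Output directory for CSV tables and the manifest
#'   (`NULL` = return results only).
#' @param use_absolute Passed to [build_comparison_table()].
#' @param nodulation_as_factor Passed to [fit_growth_model()].
#' @param sites_per_country,replicates Design sizes, see [design_config()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("harvest_consistent", "strict_formula"),
                       params = NULL, input_path = NULL,
                       S = 100000, seed = 1L, out_dir = NULL,
                       use_absolute = TRUE, nodulation_as_factor = FALSE,
                       sites_per_country = 5, replicates = 2) {
  mode <- match.arg(mode)
  if (is.null(params) == is.null(input_path)) {
    stop_rci("exactly one of `params` and `input_path` must be given",
             class = "rcindex_invalid_input")
  }
  check_scalar_number(S, "S", lower = 1000)
  check_scalar_number(seed, "seed")
  structure(list(mode = mode, params = params, input_path = input_path,
                 S = as.integer(S), seed = as.integer(seed),
                 out_dir = out_dir, use_absolute = isTRUE(use_absolute),
                 nodulation_as_factor = isTRUE(nodulation_as_factor),
                 sites_per_country = sites_per_country,
                 replicates = replicates),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: build the pot design; simulate (with early mortality) or
#' read plant records; fit one cell-means mixed model per species x soil
#' country; draw simulated coefficient vectors and propagate them into RCI
#' indices and their 50%/95% intervals; contrast introduced vs native RCI per
#' comparison cell on common draws; assemble the growth-difference vs
#' RCI-difference table; and correlate the two difference magnitudes. A
#' manifest records the configuration, derived seeds, package version and
#' per-stage row counts; rerunning with the same configuration reproduces
#' every output bit-identically.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `design`, `records`, `fits`,
#'   `rci_summaries` (data frame), `rci_diffs` (list and data frame),
#'   `comparison`, `correlation`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dcfg <- design_config(config$mode, sites_per_country = config$sites_per_country,
                        replicates = config$replicates)
  design <- build_design(dcfg)

  if (!is.null(config$params)) {
    records <- generate_dataset(design, config$params, seed = config$seed + 1L)
    records <- apply_mortality(records, config$params$mortality_rate,
                               seed = config$seed + 2L)
  } else {
    records <- read_records(config$input_path)
  }
  if (nrow(records) == 0) {
    stop_rci("stage generate/read produced no plant records",
             class = "rcindex_pipeline_error")
  }

  combos <- unique(records[, c("species", "soil_country")])
  combos <- combos[order(combos$species, combos$soil_country), , drop = FALSE]
  keys <- fit_key(combos$species, combos$soil_country)
  fits <- vector("list", length(keys))
  names(fits) <- keys
  for (i in seq_along(keys)) {
    sub <- records[records$species == combos$species[i] &
                     records$soil_country == combos$soil_country[i], ,
                   drop = FALSE]
    fits[[i]] <- tryCatch(
      fit_growth_model(sub, nodulation_as_factor = config$nodulation_as_factor),
      error = function(e) {
        stop_rci("stage fit failed for %s: %s", keys[i], conditionMessage(e),
                 class = "rcindex_pipeline_error")
      })
  }

  cells <- comparison_cells(design)
  sum_rows <- list()
  diffs <- list()
  draws_cache <- list()
  for (i in seq_len(nrow(cells))) {
    sp <- cells$species[i]; soil <- cells$soil_country[i]
    partner <- cells$native_partner[i]
    key <- fit_key(sp, soil)
    fit <- fits[[key]]
    if (is.null(fit)) {
      stop_rci("stage rci: no fit for comparison cell %s", key,
               class = "rcindex_pipeline_error")
    }
    needed <- c(rci_introduced, partner,
                paired_label(rci_introduced, partner),
                paired_label(partner, rci_introduced))
    missing <- setdiff(needed, fit$cell_labels)
    if (length(missing) > 0) {
      stop_rci("stage rci: fit %s lacks cell(s) %s", key,
               paste(missing, collapse = ", "),
               class = "rcindex_pipeline_error")
    }
    # one draw matrix per fitted model, shared by every index derived from it
    if (is.null(draws_cache[[key]])) {
      draws_seed <- config$seed + 100L + match(key, keys)
      draws_cache[[key]] <- simulate_fixed_effects(fit, S = config$S,
                                                   seed = draws_seed)
    }
    dr <- draws_cache[[key]]
    d_intro <- rci_from_draws(dr, fit, rci_introduced,
                              paired_label(rci_introduced, partner))
    d_native <- rci_from_draws(dr, fit, partner,
                               paired_label(partner, rci_introduced))
    for (d in list(d_intro, d_native)) {
      s <- summarize_rci(d)
      sum_rows[[length(sum_rows) + 1L]] <- data.frame(
        species = sp, soil_country = soil, index_label = s$index_label,
        mean = s$mean, ci50_lower = s$ci50[["lower"]],
        ci50_upper = s$ci50[["upper"]], ci95_lower = s$ci95[["lower"]],
        ci95_upper = s$ci95[["upper"]], stringsAsFactors = FALSE)
    }
    diffs[[length(diffs) + 1L]] <- rci_difference(d_intro, d_native,
                                                  native_partner = partner)
  }
  rci_summaries <- do.call(rbind, sum_rows)
  diffs_df <- do.call(rbind, lapply(diffs, function(d) data.frame(
    species = d$species, soil_country = d$soil_country,
    native_partner = d$native_partner, mean_diff = d$mean_diff,
    ci50_lower = d$ci50[["lower"]], ci50_upper = d$ci50[["upper"]],
    ci95_lower = d$ci95[["lower"]], ci95_upper = d$ci95[["upper"]],
    significant = d$significant, stringsAsFactors = FALSE)))

  comparison <- build_comparison_table(fits, diffs,
                                       use_absolute = config$use_absolute)
  correlation <- if (nrow(comparison) >= 3 &&
                     stats::sd(comparison$growth_diff) > 0 &&
                     stats::sd(comparison$rci_diff) > 0) {
    pearson_correlation(comparison$growth_diff, comparison$rci_diff)
  } else NULL

  manifest <- list(
    package = "rcindex",
    version = as.character(utils::packageVersion("rcindex")),
    mode = config$mode,
    source = if (is.null(config$input_path)) "simulate" else config$input_path,
    S = config$S,
    master_seed = config$seed,
    stage_seeds = list(data = config$seed + 1L, mortality = config$seed + 2L,
                       draws = config$seed + 100L + seq_along(keys)),
    rows = list(design = nrow(design), records = nrow(records),
                fits = length(fits), rci_summaries = nrow(rci_summaries),
                rci_differences = nrow(diffs_df),
                comparison = nrow(comparison)))

  result <- list(design = design, records = records, fits = fits,
                 rci_summaries = rci_summaries, rci_diffs = diffs,
                 rci_diffs_df = diffs_df, comparison = comparison,
                 correlation = correlation, manifest = manifest)
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config)
  invisible(result)
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  write_design(result$design, out("design.csv"))
  write_records(result$records, out("records.csv"))
  fit_dir <- out("fits")
  dir.create(fit_dir, showWarnings = FALSE)
  fit_report <- list()
  for (key in names(result$fits)) {
    fit <- result$fits[[key]]
    se <- sqrt(diag(fit$vcov_fixed))
    utils::write.csv(data.frame(term = names(fit$coefficients),
                                estimate = unname(fit$coefficients),
                                se = unname(se)),
                     file.path(fit_dir, paste0(key, "_coef.csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(fit$vcov_fixed),
                     file.path(fit_dir, paste0(key, "_vcov.csv")),
                     row.names = TRUE)
    fit_report[[key]] <- list(sigma_site = fit$sigma_site_hat,
                              sigma_resid = fit$sigma_resid_hat,
                              loglik_reml = fit$loglik_reml,
                              loglik_ml = fit$loglik_ml,
                              n_obs = fit$n_obs, fitted_by = fit$fitted_by)
  }
  jsonlite::write_json(fit_report, out("fit_report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.csv(result$rci_summaries, out("rci_summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(result$rci_diffs_df, out("rci_differences.csv"),
                   row.names = FALSE)
  utils::write.csv(result$comparison, out("comparison.csv"), row.names = FALSE)
  if (!is.null(result$correlation)) {
    utils::write.csv(data.frame(r = result$correlation$r,
                                p_value = result$correlation$p_value,
                                n = result$correlation$n),
                     out("correlation.csv"), row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}
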