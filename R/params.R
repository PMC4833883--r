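#' Generative parameters for synthetic plant-level data
#'
#' The synthetic-data generator draws log growth rates from
#' `m + beta_nod * nodulation + b_site + eps`, where `m` is the cell mean for
#' singly grown plants and `log(exp(m) * (1 - RCI))` for plants in paired
#' pots, `b_site ~ N(0, sigma_site^2)` is shared by all pots inoculated with
#' soil from one collection site, and `eps ~ N(0, sigma_resid^2)` is
#' plant-level noise. Competition is therefore injected exactly through the
#' relative competition intensity identity `GR_A(B) = GR_A * (1 - RCI_A(B))`,
#' so the inference target of the downstream pipeline is true by construction.
#'
#' @param single_log_means Named numeric vector of true mean log growth rates
#'   (log g/day, at nodulation score 0) for singly grown plants; names are
#'   `"<species>.<soil>.<provenance>"` (see [cell_key()]).
#' @param true_rci Named numeric vector of true RCI values, each `< 1`; names
#'   are `"<species>.<soil>.<focal>.<partner>"` (see [rci_key()]).
#' @param beta_nod Additive effect on log growth rate per nodulation unit.
#' @param sigma_site SD of soil-site random intercepts (log scale).
#' @param sigma_resid Residual SD (log scale).
#' @param mortality_rate Probability in `[0, 1)` of early seedling death.
#' @param growing_days Days from transplant to harvest (scalar, or named by
#'   species); the paper's plants were harvested after about 3 months.
#' @param nod_probs Probabilities of nodulation scores 0..3 (length 4).
#' @param seed Integer seed used by [generate_dataset()] unless overridden.
#' @return A list of class `true_params`.
#' @export
true_params <- function(single_log_means, true_rci = numeric(0),
                        beta_nod = 0.15, sigma_site = 0.2, sigma_resid = 0.4,
                        mortality_rate = 0.11, growing_days = 90,
                        nod_probs = rep(0.25, 4), seed = 1L) {
  if (is.null(names(single_log_means)) || anyNA(single_log_means)) {
    stop_rci("single_log_means must be a fully named, non-missing vector",
             class = "rcindex_config_error")
  }
  if (length(true_rci) > 0 && (is.null(names(true_rci)) || anyNA(true_rci))) {
    stop_rci("true_rci must be a fully named, non-missing vector",
             class = "rcindex_config_error")
  }
  if (any(true_rci >= 1)) {
    stop_rci("true_rci must be < 1 for every paired cell (offending: %s)",
             paste(names(true_rci)[true_rci >= 1], collapse = ", "),
             class = "rcindex_config_error")
  }
  check_scalar_number(beta_nod, "beta_nod")
  check_scalar_number(sigma_site, "sigma_site", lower = 0)
  check_scalar_number(sigma_resid, "sigma_resid", lower = 0)
  check_scalar_number(mortality_rate, "mortality_rate", lower = 0, upper = 1,
                      upper_open = TRUE)
  if (!is.numeric(growing_days) || any(growing_days <= 0)) {
    stop_rci("growing_days must be positive", class = "rcindex_config_error")
  }
  stopifnot(length(nod_probs) == 4, all(nod_probs >= 0), sum(nod_probs) > 0)
  structure(list(single_log_means = single_log_means,
                 true_rci = true_rci,
                 beta_nod = beta_nod,
                 sigma_site = sigma_site,
                 sigma_resid = sigma_resid,
                 mortality_rate = mortality_rate,
                 growing_days = growing_days,
                 nod_probs = nod_probs / sum(nod_probs),
                 seed = as.integer(seed)),
            class = "true_params")
}

#' Default generative parameters for a design
#'
#' Fills every single cell and every paired cell appearing in `design` with a
#' stated set of defaults: a base growth rate of 0.04 g/day modified by small
#' deterministic species and soil offsets, introduced (NZ) plants growing
#' more slowly in native-range soils (a biogeographic pattern the experiment
#' was designed to detect), and a common true RCI of 0.35 for every paired
#' cell (competition reduced growth by roughly a third in the experiment the
#' generator emulates).
#'
#' @param design A design data frame from [build_design()].
#' @param true_rci_value Default RCI for every paired cell, or a named vector
#'   overriding specific cells (names as [rci_key()]).
#' @param nz_penalty_native_soil Amount subtracted from the NZ provenance's
#'   log mean in native-range soils.
#' @param ... Passed on to [true_params()].
#' @return A `true_params` object covering all cells of `design`.
#' @export
default_true_params <- function(design = build_design(),
                                true_rci_value = 0.35,
                                nz_penalty_native_soil = 0.3, ...) {
  sp_off <- c(arvense = 0, campestre = -0.2, striatum = 0.1)
  soil_off <- c(NZ = 0, SP = -0.1, UK = -0.15)

  singles <- design[design$treatment == "single", , drop = FALSE]
  cells <- unique(data.frame(species = singles$species,
                             soil = singles$soil_country,
                             prov = singles$provenance_1,
                             stringsAsFactors = FALSE))
  m <- log(0.04) +
    ifelse(is.na(sp_off[cells$species]), 0, sp_off[cells$species]) +
    soil_off[cells$soil] -
    ifelse(cells$prov == rci_introduced & cells$soil != "NZ",
           nz_penalty_native_soil, 0)
  names(m) <- cell_key(cells$species, cells$soil, cells$prov)

  paired <- design[design$treatment == "paired", , drop = FALSE]
  pc <- unique(data.frame(species = paired$species, soil = paired$soil_country,
                          a = paired$provenance_1, b = paired$provenance_2,
                          stringsAsFactors = FALSE))
  keys <- c(rci_key(pc$species, pc$soil, pc$a, pc$b),
            rci_key(pc$species, pc$soil, pc$b, pc$a))
  if (length(names(true_rci_value)) > 0) {
    rci <- stats::setNames(rep(0.35, length(keys)), keys)
    rci[names(true_rci_value)] <- true_rci_value
    rci <- rci[names(rci) %in% keys]
  } else {
    rci <- stats::setNames(rep(true_rci_value, length(keys)), keys)
  }
  true_params(single_log_means = m, true_rci = rci, ...)
}
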