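#' Generate a synthetic plant-level dataset
#'
#' Expands a pot design into one row per plant (one for single pots, two for
#' paired pots) and draws growth rates from the log-normal mixed model
#' described in [true_params()]. The generator is a pure function of
#' `(design, params, seed)`: identical inputs give a bit-identical table.
#'
#' Draw order is fixed: soil-site intercepts first (sites in sorted order),
#' then nodulation scores for all plants (rows sorted by pot id and plant
#' slot), then residuals. Changing `beta_nod` therefore alters growth only
#' through the nodulation scores already drawn; plants with score 0 are
#' unaffected.
#'
#' @param design A design data frame ([build_design()] or compatible).
#' @param params A [true_params()] object covering every design cell.
#' @param seed Integer seed; defaults to `params$seed`.
#' @return A data frame of plant records with the design columns plus
#'   `plant_slot`, `focal_provenance`, `partner_provenance`,
#'   `nodulation_score`, `growing_days`, `dry_biomass_g`, `growth_rate`.
#' @export
generate_dataset <- function(design, params, seed = params$seed) {
  stopifnot(inherits(params, "true_params"))
  design <- design[order(design$pot_id), , drop = FALSE]

  # one row per plant
  single <- design[design$treatment == "single", , drop = FALSE]
  paired <- design[design$treatment == "paired", , drop = FALSE]
  expand_pair <- function(slot) {
    p <- paired
    p$plant_slot <- rep(slot, nrow(p))
    p$focal_provenance <- if (slot == 1) p$provenance_1 else p$provenance_2
    p$partner_provenance <- if (slot == 1) p$provenance_2 else p$provenance_1
    p
  }
  single$plant_slot <- rep(1L, nrow(single))
  single$focal_provenance <- single$provenance_1
  single$partner_provenance <- rep(NA_character_, nrow(single))
  plants <- rbind(single, expand_pair(1L), expand_pair(2L))
  plants <- plants[order(plants$pot_id, plants$plant_slot), , drop = FALSE]
  rownames(plants) <- NULL
  n <- nrow(plants)

  # expected log growth rate at nodulation 0, before site/residual noise
  skey <- cell_key(plants$species, plants$soil_country, plants$focal_provenance)
  m <- unname(params$single_log_means[skey])
  if (anyNA(m)) {
    stop_rci("no single-cell mean configured for cell(s): %s",
             paste(unique(skey[is.na(m)]), collapse = ", "),
             class = "rcindex_config_error")
  }
  is_paired <- plants$treatment == "paired"
  if (any(is_paired)) {
    rkey <- rci_key(plants$species[is_paired], plants$soil_country[is_paired],
                    plants$focal_provenance[is_paired],
                    plants$partner_provenance[is_paired])
    rci <- unname(params$true_rci[rkey])
    if (anyNA(rci)) {
      stop_rci("no true RCI configured for paired cell(s): %s",
               paste(unique(rkey[is.na(rci)]), collapse = ", "),
               class = "rcindex_config_error")
    }
    m[is_paired] <- m[is_paired] + log1p(-rci)
  }

  sites <- unique(plants[, c("soil_country", "soil_site")])
  sites <- sites[order(sites$soil_country, sites$soil_site), , drop = FALSE]
  site_id <- match(interaction(plants$soil_country, plants$soil_site,
                               drop = FALSE),
                   interaction(sites$soil_country, sites$soil_site,
                               drop = FALSE))

  with_seed(seed, {
    b_site <- stats::rnorm(nrow(sites), 0, params$sigma_site)
    nod <- sample(0:3, n, replace = TRUE, prob = params$nod_probs)
    eps <- stats::rnorm(n, 0, params$sigma_resid)
    log_gr <- m + params$beta_nod * nod + b_site[site_id] + eps

    days <- params$growing_days
    if (!is.null(names(days))) days <- unname(days[plants$species])
    plants$nodulation_score <- nod
    plants$growing_days <- as.numeric(days)
    plants$growth_rate <- exp(log_gr)
    plants$dry_biomass_g <- plants$growth_rate * plants$growing_days
  })
  plants[, c("pot_id", "soil_country", "soil_site", "species", "treatment",
             "replicate", "plant_slot", "focal_provenance",
             "partner_provenance", "nodulation_score", "growing_days",
             "dry_biomass_g", "growth_rate")]
}

#' Thin a dataset by early random mortality
#'
#' Each plant is removed independently with probability `mortality_rate`,
#' emulating early seedling mortality unrelated to treatment (about 11% in
#' the experiment this generator emulates).
#'
#' @param records A plant-record data frame.
#' @param mortality_rate Probability in `[0, 1)`.
#' @param seed Integer seed for reproducible thinning.
#' @return The surviving subset of `records`.
#' @export
apply_mortality <- function(records, mortality_rate, seed = NULL) {
  check_scalar_number(mortality_rate, "mortality_rate", lower = 0, upper = 1,
                      upper_open = TRUE)
  if (mortality_rate == 0) return(records)
  keep <- with_seed(seed, stats::runif(nrow(records)) >= mortality_rate)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
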