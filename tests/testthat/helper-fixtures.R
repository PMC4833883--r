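# Fixture builders shared across test files. Everything is generated in code
# under fixed seeds; no data files.

# One species grown in one native-range soil: the smallest slice of the
# factorial design on which the full fit -> draws -> RCI chain runs.
# Defaults mirror the study's sizes: 2 provenances x 5 sites x 2 replicates
# singles (20 pots) plus 10 paired pots.
slice_design <- function(species = "arvense", soil = "SP",
                         sites = 5, replicates = 2) {
  cfg <- design_config(species = species, sites_per_country = sites,
                       replicates = replicates)
  rbind(build_single_design(soil, cfg), build_paired_design(soil, cfg))
}

# Generative parameters for a slice: named RCI truths, defaults elsewhere.
slice_params <- function(species = "arvense", soil = "SP", partner = "SP",
                         rci_intro = 0.35, rci_native = 0.15,
                         m_native = log(0.04), m_intro = log(0.04) - 0.3,
                         ...) {
  m <- c(m_native, m_intro)
  names(m) <- cell_key(species, soil, c(partner, "NZ"))
  rci <- c(rci_intro, rci_native)
  names(rci) <- rci_key(species, soil, c("NZ", partner), c(partner, "NZ"))
  true_params(single_log_means = m, true_rci = rci, ...)
}

# Noise-free (or near-noise-free) parameters covering every design cell.
noiseless_params <- function(design, rci = 0, beta_nod = 0, sigma_site = 0,
                             sigma_resid = 0, ...) {
  default_true_params(design, true_rci_value = rci, beta_nod = beta_nod,
                      sigma_site = sigma_site, sigma_resid = sigma_resid,
                      mortality_rate = 0, ...)
}

paired_label_test <- function(focal, partner) sprintf("%s(%s)", focal, partner)

# A degenerate fitted model built directly: handy for exercising the
# Monte-Carlo machinery with exactly known inputs.
toy_fit <- function(m_single = 0, m_paired = log(0.5), vcov = NULL,
                    species = "arvense", soil = "SP") {
  b <- c(m_single, m_paired, 0.1)
  names(b) <- c("NZ", "NZ(SP)", "nodulation")
  if (is.null(vcov)) vcov <- matrix(0, 3, 3)
  growth_fit(cell_labels = c("NZ", "NZ(SP)"), coefficients = b,
             vcov_fixed = vcov, sigma_resid_hat = 0.3, n_obs = 30L,
             species = species, soil_country = soil)
}

# A fully crossed design (all three provenances grown singly in every soil,
# both pairings in every soil): the strict_formula reading extended so that
# every paired cell has its single-grown counterpart.
full_cross_design <- function(sites = 2, replicates = 2,
                              species = c("arvense", "campestre", "striatum")) {
  cfg <- design_config("strict_formula", species = species,
                       sites_per_country = sites, replicates = replicates)
  parts <- lapply(c("NZ", "SP", "UK"), function(soil) {
    g <- expand.grid(species = species, prov = c("NZ", "SP", "UK"),
                     site = seq_len(sites), rep = seq_len(replicates),
                     stringsAsFactors = FALSE)
    singles <- rcindex:::new_design(soil, g$site, g$species, "single",
                                    g$prov, NA_character_, g$rep)
    rbind(singles, build_paired_design(soil, cfg))
  })
  d <- do.call(rbind, parts)
  d[order(d$pot_id), ]
}
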