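#' Configure the factorial pot design
#'
#' The experiment grows three *Trifolium* species from an introduced (NZ) and
#' two native (SP, UK) seed provenances, in live soil inocula collected from
#' several sites in each of the three countries, with plants grown either
#' singly or in introduced-vs-native pairs.
#'
#' Two readings of the paired-pot layout are supported. `"strict_formula"`
#' crosses both native pairings (NZ x SP and NZ x UK) with every soil country,
#' giving 60 paired pots per soil at the default sizes. `"harvest_consistent"`
#' (the default) places both pairings only in NZ soil and the local pairing in
#' each native soil (NZ x SP in Spanish soil, NZ x UK in UK soil), which
#' yields exactly 12 distinct (species, soil, native partner) comparison cells
#' across the study.
#'
#' @param mode `"harvest_consistent"` or `"strict_formula"`.
#' @param species Character vector of species names.
#' @param sites_per_country Number of soil collection sites per country.
#' @param replicates Number of replicate pots per factor combination.
#' @return A list of class `design_config`.
#' @export
#' @examples
#' cfg <- design_config(sites_per_country = 1, replicates = 1)
#' nrow(build_single_design("NZ", cfg))  # 9
design_config <- function(mode = c("harvest_consistent", "strict_formula"),
                          species = rci_species,
                          sites_per_country = 5,
                          replicates = 2) {
  mode <- match.arg(mode)
  check_scalar_number(sites_per_country, "sites_per_country", lower = 1)
  check_scalar_number(replicates, "replicates", lower = 1)
  structure(list(mode = mode,
                 species = as.character(species),
                 sites_per_country = as.integer(sites_per_country),
                 replicates = as.integer(replicates)),
            class = "design_config")
}

check_soil <- function(soil_country) {
  if (!(is.character(soil_country) && length(soil_country) == 1L &&
        soil_country %in% rci_soils)) {
    stop_rci("unknown soil country %s; must be one of %s",
             deparse(soil_country), paste(rci_soils, collapse = ", "),
             class = "rcindex_invalid_input")
  }
  soil_country
}

# Provenances grown singly in each soil: all three in the introduced range,
# the introduced plus the local native provenance in each native range.
single_provenances <- function(soil_country) {
  switch(soil_country,
         NZ = c("NZ", "SP", "UK"),
         SP = c("NZ", "SP"),
         UK = c("NZ", "UK"))
}

# Native partners paired against the introduced provenance in each soil.
paired_partners <- function(soil_country, mode) {
  if (mode == "strict_formula") return(c("SP", "UK"))
  switch(soil_country, NZ = c("SP", "UK"), SP = "SP", UK = "UK")
}

make_pot_id <- function(soil_country, soil_site, species, treatment,
                        prov1, prov2, replicate) {
  prov <- ifelse(is.na(prov2), prov1, paste0(prov1, "x", prov2))
  sprintf("%s-s%d-%s-%s-%s-r%d", soil_country, soil_site, species,
          substr(treatment, 1, 3), prov, replicate)
}

new_design <- function(soil_country, soil_site, species, treatment,
                       prov1, prov2, replicate) {
  d <- data.frame(soil_country = soil_country,
                  soil_site = as.integer(soil_site),
                  species = species,
                  treatment = treatment,
                  provenance_1 = prov1,
                  provenance_2 = prov2,
                  replicate = as.integer(replicate),
                  stringsAsFactors = FALSE)
  d$pot_id <- make_pot_id(d$soil_country, d$soil_site, d$species, d$treatment,
                          d$provenance_1, d$provenance_2, d$replicate)
  d <- d[order(d$pot_id), c("pot_id", "soil_country", "soil_site", "species",
                            "treatment", "provenance_1", "provenance_2",
                            "replicate")]
  rownames(d) <- NULL
  d
}

#' Build the single-plant pot design for one soil country
#'
#' Fully crosses species x provenance x soil site x replicate, where the
#' provenance set depends on the soil: all three provenances in NZ soil
#' (90 pots at default sizes), the introduced plus the local native
#' provenance in each native-range soil (60 pots each).
#'
#' @param soil_country One of `"NZ"`, `"SP"`, `"UK"`.
#' @param config A [design_config()].
#' @return A data frame with one row per pot (`treatment == "single"`,
#'   `provenance_2` is `NA`).
#' @export
build_single_design <- function(soil_country, config = design_config()) {
  check_soil(soil_country)
  stopifnot(inherits(config, "design_config"))
  g <- expand.grid(species = config$species,
                   provenance = single_provenances(soil_country),
                   soil_site = seq_len(config$sites_per_country),
                   replicate = seq_len(config$replicates),
                   stringsAsFactors = FALSE)
  new_design(soil_country, g$soil_site, g$species, "single",
             g$provenance, NA_character_, g$replicate)
}

#' Build the paired-plant pot design for one soil country
#'
#' Every paired pot contains one plant from the introduced provenance (NZ)
#' and one from a native provenance (SP or UK); which pairings occur in which
#' soil depends on `config$mode` (see [design_config()]).
#'
#' @inheritParams build_single_design
#' @return A data frame with one row per pot (`treatment == "paired"`,
#'   `provenance_1 == "NZ"`, `provenance_2` the native partner).
#' @export
build_paired_design <- function(soil_country, config = design_config()) {
  check_soil(soil_country)
  stopifnot(inherits(config, "design_config"))
  g <- expand.grid(species = config$species,
                   partner = paired_partners(soil_country, config$mode),
                   soil_site = seq_len(config$sites_per_country),
                   replicate = seq_len(config$replicates),
                   stringsAsFactors = FALSE)
  new_design(soil_country, g$soil_site, g$species, "paired",
             rci_introduced, g$partner, g$replicate)
}

#' Build the full design across all three soils
#'
#' @param config A [design_config()].
#' @return A data frame of single- and paired-plant pots over all soils.
#' @export
build_design <- function(config = design_config()) {
  parts <- lapply(rci_soils, function(s) {
    rbind(build_single_design(s, config), build_paired_design(s, config))
  })
  d <- do.call(rbind, parts)
  d <- d[order(d$pot_id), ]
  rownames(d) <- NULL
  d
}

#' Count pots by soil country and treatment
#'
#' @param design A design data frame (possibly empty).
#' @return A data frame with columns `soil_country`, `treatment`, `n`;
#'   always one row per soil x treatment combination, zero counts included.
#' @export
count_pots <- function(design) {
  tab <- table(factor(design$soil_country, levels = rci_soils),
               factor(design$treatment, levels = c("single", "paired")))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("soil_country", "treatment", "n")
  out$n <- as.integer(out$n)
  out[order(out$soil_country, out$treatment), ]
}

#' Enumerate the between-provenance comparison cells of a design
#'
#' Each paired pot defines a (species, soil country, native partner)
#' comparison cell: the cell in which the introduced provenance's RCI is
#' contrasted with the native partner's. The harvest_consistent design yields
#' 12 distinct cells.
#'
#' @param design A design data frame containing paired pots.
#' @return A data frame with columns `species`, `soil_country`,
#'   `native_partner`, one row per distinct cell.
#' @export
comparison_cells <- function(design) {
  p <- design[design$treatment == "paired", , drop = FALSE]
  cells <- unique(data.frame(species = p$species,
                             soil_country = p$soil_country,
                             native_partner = p$provenance_2,
                             stringsAsFactors = FALSE))
  cells <- cells[order(cells$species, cells$soil_country,
                       cells$native_partner), ]
  rownames(cells) <- NULL
  cells
}

#' Write / read a pot design as tidy CSV
#'
#' One row per pot; the empty string encodes a missing `provenance_2`.
#'
#' @param design A design data frame.
#' @param path File path.
#' @return `read_design` returns the design data frame.
#' @export
write_design <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  required <- c("pot_id", "soil_country", "soil_site", "species", "treatment",
                "provenance_1", "provenance_2", "replicate")
  missing <- setdiff(required, names(d))
  if (length(missing) > 0) {
    stop_rci("design file %s lacks column(s): %s", path,
             paste(missing, collapse = ", "), class = "rcindex_parse_error")
  }
  d$soil_site <- as.integer(d$soil_site)
  d$replicate <- as.integer(d$replicate)
  bad_single <- which(d$treatment == "single" & !is.na(d$provenance_2))
  bad_paired <- which(d$treatment == "paired" & is.na(d$provenance_2))
  if (length(c(bad_single, bad_paired)) > 0) {
    stop_rci("design row(s) %s violate the single/paired provenance rule",
             paste(c(bad_single, bad_paired), collapse = ", "),
             class = "rcindex_validation_error")
  }
  d[, required]
}
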