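record_columns <- c("pot_id", "soil_country", "soil_site", "species",
                    "treatment", "replicate", "plant_slot",
                    "focal_provenance", "partner_provenance",
                    "nodulation_score", "growing_days", "dry_biomass_g",
                    "growth_rate")

#' Write / read plant records as tidy CSV
#'
#' One row per plant; a missing partner provenance (single pots) is encoded
#' as an empty field. On read, `growth_rate` is recomputed as
#' `dry_biomass_g / growing_days` and the record invariants are checked:
#' positive biomass and growing days, nodulation scores in 0..3, and a
#' partner provenance present if and only if the pot is paired. Violations
#' are reported with their row numbers.
#'
#' @param records A plant-record data frame.
#' @param path CSV file path.
#' @return `read_records` returns the validated data frame.
#' @export
write_records <- function(records, path) {
  out <- records[, record_columns]
  # 17 significant digits so doubles survive the text round trip bit-exactly
  for (col in c("growing_days", "dry_biomass_g", "growth_rate")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  d <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, na.strings = ""),
    error = function(e) {
      stop_rci("cannot parse %s: %s", path, conditionMessage(e),
               class = "rcindex_parse_error")
    })
  missing <- setdiff(record_columns, names(d))
  if (length(missing) > 0) {
    stop_rci("records file %s lacks column(s): %s", path,
             paste(missing, collapse = ", "), class = "rcindex_parse_error")
  }
  for (col in c("soil_site", "replicate", "plant_slot", "nodulation_score")) {
    d[[col]] <- as.integer(d[[col]])
  }
  for (col in c("growing_days", "dry_biomass_g", "growth_rate")) {
    d[[col]] <- as.numeric(d[[col]])
  }
  # growth_rate is recomputed and checked against the stored value inside
  # validate_records; the stored (full-precision) value is kept so that a
  # write/read round trip is bit-exact
  validate_records(d)
  d[, record_columns]
}

#' Validate plant-record invariants
#'
#' @param records A plant-record data frame.
#' @return `records`, invisibly; stops with row numbers on violation.
#' @export
validate_records <- function(records) {
  problems <- character(0)
  flag <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      rows <- which(bad)
      problems <<- c(problems, sprintf("%s (row %s)", what,
                                       paste(rows, collapse = ", ")))
    }
  }
  flag(!(records$dry_biomass_g > 0), "dry_biomass_g must be > 0")
  flag(!(records$growing_days > 0), "growing_days must be > 0")
  flag(!records$nodulation_score %in% 0:3, "nodulation_score must be in 0..3")
  flag(records$treatment == "single" & !is.na(records$partner_provenance),
       "single-pot plant has a partner provenance")
  flag(records$treatment == "paired" & is.na(records$partner_provenance),
       "paired-pot plant lacks a partner provenance")
  flag(!records$soil_country %in% rci_soils, "unknown soil country")
  flag(!records$focal_provenance %in% rci_provenances, "unknown provenance")
  rel_err <- abs(records$growth_rate -
                   records$dry_biomass_g / records$growing_days)
  flag(rel_err > 1e-8 * pmax(records$growth_rate, 1e-12),
       "growth_rate != dry_biomass_g / growing_days")
  if (length(problems) > 0) {
    stop_rci("invalid plant records: %s", paste(problems, collapse = "; "),
             class = "rcindex_validation_error")
  }
  invisible(records)
}
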