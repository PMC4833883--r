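#' @keywords internal
"_PACKAGE"

# Factor levels of the experiment. Soil countries double as provenance labels:
# NZ is the introduced range, SP and UK the native ranges.
rci_soils <- c("NZ", "SP", "UK")
rci_species <- c("arvense", "campestre", "striatum")
rci_provenances <- c("NZ", "SP", "UK")
rci_introduced <- "NZ"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state so
# seeded operations do not perturb the global random stream. seed = NULL means
# use the current stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

stop_rci <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "rcindex_error"),
                      call = sys.call(-1)))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                lower_open = FALSE, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_rci("`%s` must be a single non-missing number", name,
             class = "rcindex_invalid_input")
  }
  lo_ok <- if (lower_open) x > lower else x >= lower
  hi_ok <- if (upper_open) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop_rci("`%s` = %g is outside its allowed range", name, x,
             class = "rcindex_invalid_input")
  }
  invisible(x)
}

#' Lookup keys for parameter maps and fit lists
#'
#' Flat, dot-separated keys used to name entries of the generative parameter
#' maps (`single_log_means`, `true_rci`) and lists of fitted models.
#'
#' @param species,soil_country,provenance,focal,partner Factor labels.
#' @return A character vector of keys.
#' @export
cell_key <- function(species, soil_country, provenance) {
  paste(species, soil_country, provenance, sep = ".")
}

#' @rdname cell_key
#' @export
rci_key <- function(species, soil_country, focal, partner) {
  paste(species, soil_country, focal, partner, sep = ".")
}

#' @rdname cell_key
#' @export
fit_key <- function(species, soil_country) {
  paste(species, soil_country, sep = ".")
}

paired_label <- function(focal, partner) {
  sprintf("%s(%s)", focal, partner)
}
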