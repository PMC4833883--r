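#' Build the growth-difference vs RCI-difference comparison table
#'
#' One row per (species, soil country, native partner) comparison cell:
#' `growth_diff` is the difference between the back-transformed,
#' nodulation-adjusted single-grown cell means of the introduced and native
#' provenances (g/day; introduced minus native), and `rci_diff` is the mean
#' of the corresponding RCI contrast. With `use_absolute` (the default) both
#' columns are absolute magnitudes, since signed differences carry arbitrary
#' sign conventions across soils.
#'
#' @param fits Named list of [growth_fit()] objects, names
#'   `"<species>.<soil>"` as produced by [fit_key()].
#' @param rci_diffs List of [rci_difference()] summaries.
#' @param use_absolute Take absolute values of both difference columns.
#' @param log_scale Compute `growth_diff` on the log scale instead of
#'   back-transforming to g/day.
#' @return A data frame with columns `species`, `soil_country`,
#'   `native_partner`, `growth_diff`, `rci_diff`.
#' @export
build_comparison_table <- function(fits, rci_diffs, use_absolute = TRUE,
                                   log_scale = FALSE) {
  rows <- lapply(rci_diffs, function(d) {
    stopifnot(inherits(d, "rci_diff_summary"))
    key <- fit_key(d$species, d$soil_country)
    fit <- fits[[key]]
    if (is.null(fit)) {
      stop_rci("no growth fit supplied for cell %s", key,
               class = "rcindex_invalid_input")
    }
    for (cl in c(rci_introduced, d$native_partner)) {
      if (!cl %in% fit$cell_labels) {
        stop_rci("fit %s lacks single-grown cell %s", key, cl,
                 class = "rcindex_invalid_input")
      }
    }
    m_intro <- fit$coefficients[[rci_introduced]]
    m_native <- fit$coefficients[[d$native_partner]]
    gd <- if (log_scale) m_intro - m_native else exp(m_intro) - exp(m_native)
    data.frame(species = d$species, soil_country = d$soil_country,
               native_partner = d$native_partner,
               growth_diff = gd, rci_diff = d$mean_diff,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  key <- paste(out$species, out$soil_country, out$native_partner)
  if (anyDuplicated(key)) {
    stop_rci("duplicate comparison cell(s): %s",
             paste(unique(key[duplicated(key)]), collapse = ", "),
             class = "rcindex_invalid_input")
  }
  if (use_absolute) {
    out$growth_diff <- abs(out$growth_diff)
    out$rci_diff <- abs(out$rci_diff)
  }
  out <- out[order(out$species, out$soil_country, out$native_partner), ]
  rownames(out) <- NULL
  out
}

#' Pearson correlation with a t-based p-value
#'
#' Standard product-moment correlation; two-sided p-value from the t
#' distribution on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return An object of class `correlation_result` with `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    stop_rci("x and y differ in length", class = "rcindex_invalid_input")
  }
  n <- length(x)
  if (n < 3) {
    stop_rci("need at least 3 pairs for a p-value (got %d)", n,
             class = "rcindex_invalid_input")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_rci("correlation undefined: zero variance in an input",
             class = "rcindex_domain_error")
  }
  r <- stats::cor(x, y)
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  p <- if (abs(r) == 1) 0 else 2 * stats::pt(-abs(t_stat), df = n - 2)
  structure(list(r = r, p_value = p, n = n, statistic = t_stat,
                 df = n - 2L),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson's correlation = %.2f; P = %.3g; N = %d\n",
              x$r, x$p_value, x$n))
  invisible(x)
}
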