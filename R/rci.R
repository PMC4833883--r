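#' Relative competition intensity
#'
#' `RCI_A(B) = (GR_A - GR_A(B)) / GR_A`, where `GR_A` is the growth rate of a
#' plant from provenance A grown alone and `GR_A(B)` its growth rate in
#' competition with provenance B. 0 means no competitive effect, the maximum
#' of 1 complete suppression, and negative values facilitation (A grew better
#' with B than alone).
#'
#' @param gr_alone Growth rate grown alone (g/day), strictly positive.
#' @param gr_with Growth rate in competition (g/day), nonnegative.
#' @return The dimensionless index, vectorised over its arguments.
#' @export
#' @examples
#' compute_rci(0.10, 0.10)  # 0: no competitive effect
#' compute_rci(0.10, 0.00)  # 1: complete suppression
#' compute_rci(0.20, 0.30)  # -0.5: facilitation
compute_rci <- function(gr_alone, gr_with) {
  if (!is.numeric(gr_alone) || !is.numeric(gr_with)) {
    stop_rci("growth rates must be numeric", class = "rcindex_invalid_input")
  }
  if (any(gr_alone <= 0)) {
    stop_rci("gr_alone must be > 0", class = "rcindex_domain_error")
  }
  if (any(gr_with < 0)) {
    stop_rci("gr_with must be >= 0", class = "rcindex_domain_error")
  }
  (gr_alone - gr_with) / gr_alone
}

#' Draw simulated fixed-effect vectors from a fitted growth model
#'
#' Samples `S` coefficient vectors from the multivariate normal distribution
#' with mean the fitted coefficients and covariance the fixed-effects
#' variance-covariance matrix, the parametric simulation step that propagates
#' estimation uncertainty into derived indices. The matrix is symmetrised and
#' eigenvalues within numerical tolerance of zero are clipped; a genuinely
#' indefinite matrix is an error.
#'
#' @param fit A [growth_fit()].
#' @param S Number of draws (default 100,000).
#' @param seed Integer seed for reproducible draws.
#' @return An `S` x `p` matrix, columns named like the coefficients, with the
#'   seed stored in attribute `"seed"`.
#' @export
simulate_fixed_effects <- function(fit, S = 100000, seed = NULL) {
  stopifnot(inherits(fit, "growth_fit"))
  check_scalar_number(S, "S", lower = 1)
  V <- (fit$vcov_fixed + t(fit$vcov_fixed)) / 2
  eg <- eigen(V, symmetric = TRUE)
  tol <- 1e-8 * max(abs(eg$values), 1)
  if (min(eg$values) < -tol) {
    stop_rci("vcov_fixed is not positive semidefinite (smallest eigenvalue %g)",
             min(eg$values), class = "rcindex_numerical_error")
  }
  vals <- pmax(eg$values, 0)
  V <- eg$vectors %*% (vals * t(eg$vectors))
  draws <- with_seed(seed, MASS::mvrnorm(S, mu = fit$coefficients, Sigma = V))
  if (S == 1) draws <- matrix(draws, nrow = 1)
  colnames(draws) <- names(fit$coefficients)
  attr(draws, "seed") <- seed
  draws
}

#' Compute RCI draws for one index from simulated coefficients
#'
#' For each simulated coefficient vector, back-transforms the single-grown
#' and in-competition log cell means by exponentiation and applies
#' [compute_rci()]. The nodulation term is excluded: cell means are already
#' nodulation-adjusted (expected log growth at score 0), so the slope cancels
#' from the ratio. Algebraically each draw equals
#' `1 - exp(m_paired - m_single)`.
#'
#' @param draws Matrix from [simulate_fixed_effects()].
#' @param fit The [growth_fit()] the draws came from.
#' @param single_cell Label of the focal provenance's single-grown cell,
#'   e.g. `"NZ"`.
#' @param paired_cell Label of its in-competition cell, e.g. `"NZ(SP)"`.
#' @return An object of class `rci_draws`: the index label, the vector of
#'   simulated RCI values, `S`, and the seed.
#' @export
rci_from_draws <- function(draws, fit, single_cell, paired_cell) {
  stopifnot(inherits(fit, "growth_fit"))
  for (cl in c(single_cell, paired_cell)) {
    if (!cl %in% fit$cell_labels) {
      stop_rci("unknown cell label %s; available: %s", deparse(cl),
               paste(fit$cell_labels, collapse = ", "),
               class = "rcindex_invalid_input")
    }
  }
  values <- 1 - exp(draws[, paired_cell] - draws[, single_cell])
  structure(list(index_label = paired_cell,
                 values = as.numeric(values),
                 S = length(values),
                 seed = attr(draws, "seed"),
                 species = fit$species,
                 soil_country = fit$soil_country),
            class = "rci_draws")
}

#' Summarise RCI draws
#'
#' Mean plus equal-tailed quantile intervals at 50% (0.25/0.75 quantiles) and
#' 95% (0.025/0.975); quantile intervals rather than normal approximations
#' because the draw distribution of a ratio is skewed.
#'
#' @param rci_draws An `rci_draws` object (or bare numeric vector).
#' @return An object of class `rci_summary` with `mean`, `ci50`, `ci95`.
#' @export
summarize_rci <- function(rci_draws) {
  values <- if (inherits(rci_draws, "rci_draws")) rci_draws$values else rci_draws
  if (length(values) == 0) {
    stop_rci("no draws to summarise", class = "rcindex_invalid_input")
  }
  q <- stats::quantile(values, c(0.025, 0.25, 0.75, 0.975), names = FALSE)
  structure(list(index_label = if (inherits(rci_draws, "rci_draws"))
                   rci_draws$index_label else NA_character_,
                 species = if (inherits(rci_draws, "rci_draws"))
                   rci_draws$species else NA_character_,
                 soil_country = if (inherits(rci_draws, "rci_draws"))
                   rci_draws$soil_country else NA_character_,
                 mean = mean(values),
                 ci50 = c(lower = q[2], upper = q[3]),
                 ci95 = c(lower = q[1], upper = q[4])),
            class = "rci_summary")
}

#' @export
print.rci_summary <- function(x, ...) {
  cat(sprintf("RCI %s [%s, %s soil]: mean %.3f, 50%% CI (%.3f, %.3f), 95%% CI (%.3f, %.3f)\n",
              x$index_label, x$species, x$soil_country, x$mean,
              x$ci50[1], x$ci50[2], x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Contrast introduced vs native RCI draws
#'
#' Computes, draw by draw, `RCI_introduced(native) - RCI_native(introduced)`.
#' The two indices should come from the same simulated coefficient matrix
#' (common random numbers), so the per-draw difference removes the shared
#' Monte-Carlo variation. A value of zero means no difference in competitive
#' ability; positive values mean the native provenance was more competitive
#' (the introduced plant suffered more from competition), negative values the
#' introduced provenance. The difference is flagged significant when the 95%
#' interval excludes zero.
#'
#' @param draws_introduced `rci_draws` for the introduced provenance's index.
#' @param draws_native `rci_draws` for the native provenance's index.
#' @param native_partner Native provenance label (defaults to the label
#'   parsed from `draws_native`).
#' @return An object of class `rci_diff_summary` with `mean_diff`, `ci50`,
#'   `ci95`, `significant`, and the cell metadata.
#' @export
rci_difference <- function(draws_introduced, draws_native,
                           native_partner = NULL) {
  stopifnot(inherits(draws_introduced, "rci_draws"),
            inherits(draws_native, "rci_draws"))
  if (draws_introduced$S != draws_native$S) {
    stop_rci("draw vectors differ in length (%d vs %d)",
             draws_introduced$S, draws_native$S,
             class = "rcindex_invalid_input")
  }
  diff <- draws_introduced$values - draws_native$values
  s <- summarize_rci(diff)
  if (is.null(native_partner)) {
    native_partner <- sub("\\(.*$", "", draws_native$index_label)
  }
  structure(list(species = draws_introduced$species,
                 soil_country = draws_introduced$soil_country,
                 native_partner = native_partner,
                 mean_diff = s$mean,
                 ci50 = s$ci50,
                 ci95 = s$ci95,
                 significant = s$ci95[["lower"]] > 0 || s$ci95[["upper"]] < 0),
            class = "rci_diff_summary")
}

#' @export
print.rci_diff_summary <- function(x, ...) {
  cat(sprintf("RCI difference (%s, %s soil, vs %s): %.3f, 95%% CI (%.3f, %.3f)%s\n",
              x$species, x$soil_country, x$native_partner, x$mean_diff,
              x$ci95[1], x$ci95[2], if (x$significant) " *" else ""))
  invisible(x)
}
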