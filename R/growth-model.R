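#' Construct a growth-model fit object
#'
#' Container for a fitted no-intercept cell-means model of log growth rates:
#' one coefficient per cell (a provenance for singly grown plants, a
#' focal(partner) combination for plants in paired pots), one or more
#' nodulation terms, the fixed-effects variance-covariance matrix, and the
#' variance components. Usually produced by [fit_growth_model()]; the
#' constructor is exported so that degenerate fits (for example with a zero
#' covariance matrix) can be built directly.
#'
#' @param cell_labels Character vector of unique cell names.
#' @param coefficients Named numeric vector: the cell means (log g/day at
#'   nodulation 0) followed by the nodulation term(s).
#' @param vcov_fixed Symmetric positive semidefinite matrix over
#'   `coefficients`.
#' @param sigma_site_hat,sigma_resid_hat Nonnegative SDs (log scale).
#' @param loglik_reml,loglik_ml Log-likelihoods (may be `NA` for OLS fits).
#' @param n_obs Number of observations.
#' @param fitted_by `"reml_mixed"` or `"ols_fallback"`.
#' @param species,soil_country Metadata carried through to RCI labels.
#' @return An object of class `growth_fit`.
#' @export
growth_fit <- function(cell_labels, coefficients, vcov_fixed,
                       sigma_site_hat = 0, sigma_resid_hat = 0,
                       loglik_reml = NA_real_, loglik_ml = NA_real_,
                       n_obs = NA_integer_, fitted_by = "reml_mixed",
                       species = NA_character_, soil_country = NA_character_) {
  vcov_fixed <- as.matrix(vcov_fixed)
  p <- length(coefficients)
  if (anyDuplicated(cell_labels)) {
    stop_rci("cell labels must be unique", class = "rcindex_invalid_input")
  }
  if (!all(cell_labels %in% names(coefficients))) {
    stop_rci("every cell label needs a coefficient",
             class = "rcindex_invalid_input")
  }
  if (!all(dim(vcov_fixed) == c(p, p))) {
    stop_rci("vcov_fixed must be %d x %d", p, p,
             class = "rcindex_invalid_input")
  }
  if (max(abs(vcov_fixed - t(vcov_fixed))) > 1e-8 * max(abs(vcov_fixed), 1)) {
    stop_rci("vcov_fixed must be symmetric", class = "rcindex_invalid_input")
  }
  dimnames(vcov_fixed) <- list(names(coefficients), names(coefficients))
  check_scalar_number(sigma_site_hat, "sigma_site_hat", lower = 0)
  check_scalar_number(sigma_resid_hat, "sigma_resid_hat", lower = 0)
  structure(list(cell_labels = cell_labels, coefficients = coefficients,
                 vcov_fixed = vcov_fixed, sigma_site_hat = sigma_site_hat,
                 sigma_resid_hat = sigma_resid_hat,
                 loglik_reml = loglik_reml, loglik_ml = loglik_ml,
                 n_obs = as.integer(n_obs), fitted_by = fitted_by,
                 species = species, soil_country = soil_country),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Cell-means growth model (%s): %s in %s soil, n = %d\n",
              x$fitted_by, x$species, x$soil_country, x$n_obs))
  se <- sqrt(diag(x$vcov_fixed))
  print(data.frame(estimate = x$coefficients, se = se))
  cat(sprintf("sigma_site = %.4f, sigma_resid = %.4f\n",
              x$sigma_site_hat, x$sigma_resid_hat))
  invisible(x)
}

# Shared model-frame builder: cell labels, log response, nodulation term.
growth_model_frame <- function(records, nodulation_as_factor) {
  cell <- ifelse(records$treatment == "single",
                 records$focal_provenance,
                 paired_label(records$focal_provenance,
                              records$partner_provenance))
  nod <- if (nodulation_as_factor) {
    factor(records$nodulation_score, levels = 0:3)
  } else {
    as.numeric(records$nodulation_score)
  }
  data.frame(log_gr = log(records$growth_rate),
             cell = factor(cell, levels = sort(unique(cell))),
             nod = nod,
             prov = factor(records$focal_provenance),
             site = factor(records$soil_site))
}

lmer_quiet_control <- function() {
  lme4::lmerControl(check.conv.singular = "ignore",
                    check.conv.grad = "ignore",
                    check.conv.hess = "ignore")
}

# Rename design-matrix coefficient names to cell labels / nodulation terms.
relabel_coefs <- function(b, cells) {
  nm <- names(b)
  nm <- sub("^cell", "", nm)
  nm[nm == "nod"] <- "nodulation"
  nm <- sub("^nod([0-9])$", "nodulation_\\1", nm)
  names(b) <- nm
  b
}

#' Fit the cell-means mixed model to log growth rates
#'
#' Fits, by REML, `log(growth_rate) ~ 0 + cell + nodulation + (1 | site)` to
#' the plants of one species grown in one soil country: no intercept, one
#' mean per provenance (single pots) or provenance combination (paired pots),
#' a nodulation covariate so cell means are interpretable as expected log
#' growth rate at nodulation score 0, and a soil-site random intercept. When
#' only one soil site is present the random effect is inestimable and the fit
#' falls back to ordinary least squares on the same design matrix, with a
#' warning.
#'
#' @param records Plant records for a single species x soil country.
#' @param include_paired Keep plants from paired pots (default) or restrict
#'   to singly grown plants.
#' @param nodulation_as_factor Treat the 0-3 nodulation score as a 4-level
#'   factor rather than a numeric linear covariate.
#' @return A [growth_fit()] object.
#' @export
fit_growth_model <- function(records, include_paired = TRUE,
                             nodulation_as_factor = FALSE) {
  if (length(unique(records$species)) != 1L ||
      length(unique(records$soil_country)) != 1L) {
    stop_rci("records must come from one species in one soil country",
             class = "rcindex_invalid_input")
  }
  if (!include_paired) {
    records <- records[records$treatment == "single", , drop = FALSE]
  }
  if (nrow(records) == 0) {
    stop_rci("no observations to fit", class = "rcindex_invalid_input")
  }
  mf <- growth_model_frame(records, nodulation_as_factor)
  cells <- levels(mf$cell)
  n_sites <- length(unique(mf$site))

  if (n_sites >= 2) {
    fit <- suppressMessages(lme4::lmer(
      log_gr ~ 0 + cell + nod + (1 | site), data = mf, REML = TRUE,
      control = lmer_quiet_control()))
    b <- relabel_coefs(lme4::fixef(fit), cells)
    V <- as.matrix(stats::vcov(fit))
    dimnames(V) <- list(names(b), names(b))
    vc <- as.data.frame(lme4::VarCorr(fit))
    sigma_site <- vc$sdcor[vc$grp == "site"][1]
    ml <- suppressMessages(lme4::refitML(fit))
    growth_fit(cells, b, V,
               sigma_site_hat = sigma_site,
               sigma_resid_hat = stats::sigma(fit),
               loglik_reml = as.numeric(stats::logLik(fit)),
               loglik_ml = as.numeric(stats::logLik(ml)),
               n_obs = nrow(mf), fitted_by = "reml_mixed",
               species = records$species[1],
               soil_country = records$soil_country[1])
  } else {
    warning("only one soil site present; falling back to OLS (no random effect)",
            call. = FALSE)
    fit <- stats::lm(log_gr ~ 0 + cell + nod, data = mf)
    b <- relabel_coefs(stats::coef(fit), cells)
    V <- stats::vcov(fit)
    dimnames(V) <- list(names(b), names(b))
    growth_fit(cells, b, V,
               sigma_site_hat = 0,
               sigma_resid_hat = stats::sigma(fit),
               loglik_reml = NA_real_,
               loglik_ml = as.numeric(stats::logLik(fit)),
               n_obs = nrow(mf), fitted_by = "ols_fallback",
               species = records$species[1],
               soil_country = records$soil_country[1])
  }
}

#' Test for a provenance effect on growth of singly grown plants
#'
#' Compares growth rates among seed provenances within one species x soil
#' country, adjusting for nodulation and soil-site effects. Two routes are
#' computed: a Wald F test of equality of the provenance cell means from the
#' REML fit, with residual denominator degrees of freedom (the default
#' reported p-value; it is well calibrated at this design's sample sizes),
#' and a maximum-likelihood likelihood-ratio chi-square comparing models with
#' and without the provenance factor (anticonservative at small n; returned
#' in `$lrt` and selectable via `method`).
#'
#' @param records Plant records; plants from paired pots are dropped.
#' @param method Which p-value populates the top-level fields.
#' @param nodulation_as_factor See [fit_growth_model()].
#' @return An object of class `provenance_test` with fields `statistic`,
#'   `df_num`, `df_den`, `p_value`, `method`, plus `$approx_f` and `$lrt`
#'   sublists carrying both routes.
#' @export
test_provenance_effect <- function(records,
                                   method = c("approx_f", "lrt_ml"),
                                   nodulation_as_factor = FALSE) {
  method <- match.arg(method)
  records <- records[records$treatment == "single", , drop = FALSE]
  provs <- unique(records$focal_provenance)
  if (length(provs) < 2) {
    stop_rci("need at least 2 provenances to test (got %s)",
             paste(provs, collapse = ", "), class = "rcindex_invalid_input")
  }
  fit <- suppressWarnings(
    fit_growth_model(records, include_paired = FALSE,
                     nodulation_as_factor = nodulation_as_factor))
  k <- length(fit$cell_labels)
  p <- length(fit$coefficients)
  # contrasts: each provenance mean minus the first
  L <- matrix(0, k - 1, p, dimnames = list(NULL, names(fit$coefficients)))
  L[, fit$cell_labels[1]] <- -1
  for (i in seq_len(k - 1)) L[i, fit$cell_labels[i + 1]] <- 1
  d <- L %*% fit$coefficients
  W <- drop(t(d) %*% solve(L %*% fit$vcov_fixed %*% t(L)) %*% d)
  df_num <- k - 1L
  df_den <- fit$n_obs - p
  f_stat <- W / df_num
  approx_f <- list(statistic = f_stat, df_num = df_num, df_den = df_den,
                   p_value = stats::pf(f_stat, df_num, df_den,
                                       lower.tail = FALSE))

  mf <- growth_model_frame(records, nodulation_as_factor)
  n_sites <- length(unique(mf$site))
  if (n_sites >= 2) {
    m1 <- suppressMessages(lme4::lmer(log_gr ~ prov + nod + (1 | site),
                                      data = mf, REML = FALSE,
                                      control = lmer_quiet_control()))
    m0 <- suppressMessages(lme4::lmer(log_gr ~ nod + (1 | site),
                                      data = mf, REML = FALSE,
                                      control = lmer_quiet_control()))
  } else {
    m1 <- stats::lm(log_gr ~ prov + nod, data = mf)
    m0 <- stats::lm(log_gr ~ nod, data = mf)
  }
  chisq <- 2 * (as.numeric(stats::logLik(m1)) - as.numeric(stats::logLik(m0)))
  chisq <- max(chisq, 0)
  lrt <- list(statistic = chisq, df_num = df_num, df_den = NA_integer_,
              p_value = stats::pchisq(chisq, df_num, lower.tail = FALSE))

  primary <- if (method == "approx_f") approx_f else lrt
  structure(list(statistic = primary$statistic, df_num = primary$df_num,
                 df_den = primary$df_den, p_value = primary$p_value,
                 method = method, approx_f = approx_f, lrt = lrt,
                 species = records$species[1],
                 soil_country = records$soil_country[1]),
            class = "provenance_test")
}

#' @export
print.provenance_test <- function(x, ...) {
  if (x$method == "approx_f") {
    cat(sprintf("Provenance effect (%s, %s soil): F(%d,%d) = %.3f, p = %.4g\n",
                x$species, x$soil_country, x$df_num, x$df_den, x$statistic,
                x$p_value))
  } else {
    cat(sprintf("Provenance effect (%s, %s soil): LRT chisq(%d) = %.3f, p = %.4g\n",
                x$species, x$soil_country, x$df_num, x$statistic, x$p_value))
  }
  invisible(x)
}
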