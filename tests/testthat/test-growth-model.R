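test_that("noiseless data recover the generating cell means", {
  d <- slice_design()
  p <- slice_params(rci_intro = 0.35, rci_native = 0.15, sigma_site = 1e-8,
                    sigma_resid = 1e-8, beta_nod = 0, mortality_rate = 0)
  rec <- generate_dataset(d, p)
  fit <- fit_growth_model(rec)
  expect_setequal(fit$cell_labels, c("NZ", "SP", "NZ(SP)", "SP(NZ)"))
  m <- p$single_log_means
  truth <- c(
    "NZ" = unname(m[cell_key("arvense", "SP", "NZ")]),
    "SP" = unname(m[cell_key("arvense", "SP", "SP")]),
    "NZ(SP)" = unname(m[cell_key("arvense", "SP", "NZ")]) + log1p(-0.35),
    "SP(NZ)" = unname(m[cell_key("arvense", "SP", "SP")]) + log1p(-0.15))
  expect_equal(fit$coefficients[names(truth)], truth, tolerance = 1e-6)
  expect_equal(fit$fitted_by, "reml_mixed")
})

test_that("mixed-model coefficients equal the brute-force GLS solution", {
  # 12-row fixture: 2 provenances x 2 sites x 3 replicates, singles only
  d <- slice_design(sites = 2, replicates = 3)
  d <- d[d$treatment == "single", ]
  p <- slice_params(sigma_site = 0.25, sigma_resid = 0.35, beta_nod = 0.15,
                    mortality_rate = 0, seed = 314L)
  rec <- generate_dataset(d, p)
  expect_equal(nrow(rec), 12)
  fit <- fit_growth_model(rec)

  # independent oracle: V = sigma^2 I + sigma_site^2 Z Z', then
  # (X' V^-1 X)^-1 X' V^-1 y with the variance components fixed at their
  # REML estimates
  y <- log(rec$growth_rate)
  cell <- factor(rec$focal_provenance)
  X <- cbind(stats::model.matrix(~ 0 + cell), nod = rec$nodulation_score)
  Z <- stats::model.matrix(~ 0 + factor(rec$soil_site))
  V <- fit$sigma_resid_hat^2 * diag(nrow(rec)) +
    fit$sigma_site_hat^2 * Z %*% t(Z)
  Vi <- solve(V)
  beta_gls <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  expect_equal(unname(fit$coefficients[c("NZ", "SP", "nodulation")]),
               unname(drop(beta_gls)), tolerance = 1e-8)
  # the fixed-effects covariance is the GLS covariance
  expect_equal(unname(fit$vcov_fixed), unname(solve(t(X) %*% Vi %*% X)),
               tolerance = 1e-6)
})

test_that("the nodulation slope is recovered within 3 SE at n = 400", {
  cfg <- design_config(species = "arvense", sites_per_country = 5,
                       replicates = 20)
  d <- build_single_design("SP", cfg)  # 2 prov x 5 x 20 = 200 pots
  d <- rbind(d, build_paired_design("SP", cfg))  # + 100 pots -> 400 plants
  p <- slice_params(beta_nod = 0.2, mortality_rate = 0, seed = 2024L)
  rec <- generate_dataset(d, p)
  expect_equal(nrow(rec), 400)
  fit <- fit_growth_model(rec)
  se <- sqrt(fit$vcov_fixed["nodulation", "nodulation"])
  expect_lt(abs(fit$coefficients[["nodulation"]] - 0.2), 3 * se)
})

test_that("single-site data fall back to OLS exactly", {
  d <- slice_design(sites = 1, replicates = 6)
  rec <- generate_dataset(d, slice_params(seed = 8L))
  expect_warning(fit <- fit_growth_model(rec), "one soil site")
  expect_equal(fit$fitted_by, "ols_fallback")
  expect_equal(fit$sigma_site_hat, 0)

  mf <- data.frame(y = log(rec$growth_rate),
                   cell = ifelse(rec$treatment == "single",
                                 rec$focal_provenance,
                                 sprintf("%s(%s)", rec$focal_provenance,
                                         rec$partner_provenance)),
                   nod = rec$nodulation_score)
  ols <- stats::lm(y ~ 0 + cell + nod, data = mf)
  expect_equal(unname(fit$coefficients), unname(coef(ols)))
  expect_equal(unname(fit$vcov_fixed), unname(vcov(ols)))
})

test_that("vcov_fixed is symmetric PSD and shrinks as replication grows", {
  fits <- lapply(c(2, 10), function(reps) {
    rec <- generate_dataset(slice_design(replicates = reps),
                            slice_params(seed = 100L + reps))
    fit_growth_model(rec)
  })
  for (fit in fits) {
    V <- fit$vcov_fixed
    expect_lt(max(abs(V - t(V))), 1e-10)
    expect_gte(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values),
               -1e-12)
  }
  shared <- intersect(rownames(fits[[1]]$vcov_fixed),
                      rownames(fits[[2]]$vcov_fixed))
  expect_true(all(diag(fits[[2]]$vcov_fixed)[shared] <
                    diag(fits[[1]]$vcov_fixed)[shared]))
})

test_that("provenance test reports calibrated F and LRT routes", {
  cfg <- design_config(species = "striatum")
  d <- build_single_design("NZ", cfg)  # 3 provenances
  params <- default_true_params(d, beta_nod = 0.15, seed = 1L)
  rec <- generate_dataset(d, params, seed = 17L)
  pt <- test_provenance_effect(rec)
  expect_s3_class(pt, "provenance_test")
  expect_equal(pt$method, "approx_f")
  expect_equal(pt$df_num, 2L)
  expect_true(pt$p_value >= 0 && pt$p_value <= 1)
  expect_true(pt$lrt$p_value >= 0 && pt$lrt$p_value <= 1)
  expect_equal(pt$statistic, pt$approx_f$statistic)
  pt2 <- test_provenance_effect(rec, method = "lrt_ml")
  expect_equal(pt2$statistic, pt$lrt$statistic)

  only_nz <- rec[rec$focal_provenance == "NZ", ]
  expect_error(test_provenance_effect(only_nz), "at least 2",
               class = "rcindex_invalid_input")
})

test_that("provenance test has power against a 2-fold growth difference", {
  # delta log = log 2 between provenances, ~20 singles per dataset
  cfg <- design_config(species = "arvense")
  d <- build_single_design("SP", cfg)
  m <- c(log(0.04), log(0.04) - log(2))
  names(m) <- cell_key("arvense", "SP", c("SP", "NZ"))
  p <- true_params(m, beta_nod = 0.15, mortality_rate = 0)
  hits <- vapply(1:40, function(i) {
    rec <- generate_dataset(d, p, seed = 5000L + i)
    rec <- rec[seq_len(20), ]
    test_provenance_effect(rec)$p_value < 0.05
  }, logical(1))
  # power is reported, not asserted pointwise; it must at least beat a coin
  expect_gt(mean(hits), 0.5)
})

test_that("shuffling provenance labels behaves like the null", {
  cfg <- design_config(species = "arvense")
  d <- build_single_design("SP", cfg)
  m <- c(log(0.04), log(0.04) - log(2))
  names(m) <- cell_key("arvense", "SP", c("SP", "NZ"))
  p <- true_params(m, beta_nod = 0.15, mortality_rate = 0)
  rec <- generate_dataset(d, p, seed = 31L)
  set.seed(606)
  hits <- vapply(1:60, function(i) {
    shuffled <- rec
    shuffled$focal_provenance <- sample(rec$focal_provenance)
    test_provenance_effect(shuffled)$p_value < 0.05
  }, logical(1))
  expect_lt(mean(hits), 0.25)
})
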