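test_that("compute_rci matches its anchor values and domain", {
  expect_equal(compute_rci(0.10, 0.10), 0)
  expect_equal(compute_rci(0.10, 0.00), 1)
  expect_equal(compute_rci(0.20, 0.30), -0.5)
  expect_equal(compute_rci(c(0.1, 0.2), c(0.05, 0.1)), c(0.5, 0.5))
  expect_error(compute_rci(0, 0.1), class = "rcindex_domain_error")
  expect_error(compute_rci(-0.1, 0.1), class = "rcindex_domain_error")
  expect_error(compute_rci(0.1, -0.1), class = "rcindex_domain_error")
})

test_that("fixed-effect draws are seeded, centred and correctly scattered", {
  V <- matrix(c(0.04, 0.01, 0,
                0.01, 0.09, 0,
                0, 0, 0), 3, 3)
  fit <- toy_fit(vcov = V)

  # zero covariance: every draw is the coefficient vector
  d0 <- simulate_fixed_effects(toy_fit(), S = 50, seed = 1)
  expect_equal(dim(d0), c(50, 3))
  expect_true(all(d0[, "NZ"] == 0) && all(d0[, "NZ(SP)"] == log(0.5)))

  # determinism contract
  expect_identical(simulate_fixed_effects(fit, S = 1000, seed = 9),
                   simulate_fixed_effects(fit, S = 1000, seed = 9))
  expect_false(identical(simulate_fixed_effects(fit, S = 1000, seed = 9),
                         simulate_fixed_effects(fit, S = 1000, seed = 10)))

  # sample covariance converges to vcov entries (3 MC SEs)
  S <- 200000
  dr <- simulate_fixed_effects(fit, S = S, seed = 4)
  CV <- stats::cov(dr[, 1:2])
  for (i in 1:2) for (j in 1:2) {
    mc_se <- sqrt((V[i, i] * V[j, j] + V[i, j]^2) / S)
    expect_lt(abs(CV[i, j] - V[i, j]), 3 * mc_se)
  }
  expect_equal(colMeans(dr)[1:2], c("NZ" = 0, "NZ(SP)" = log(0.5)),
               tolerance = 0.02)

  # indefinite matrices are rejected with the offending eigenvalue
  bad <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 0), 3, 3)
  expect_error(simulate_fixed_effects(toy_fit(vcov = bad)),
               "eigenvalue", class = "rcindex_numerical_error")
})

test_that("rci_from_draws back-transforms per draw", {
  # equal single and paired means, zero vcov: all draws exactly 0
  fit_eq <- toy_fit(m_single = log(0.04), m_paired = log(0.04))
  dr <- simulate_fixed_effects(fit_eq, S = 100, seed = 2)
  expect_true(all(rci_from_draws(dr, fit_eq, "NZ", "NZ(SP)")$values == 0))

  # single mean log(1), paired mean log(0.5): all draws 0.5
  fit_h <- toy_fit(m_single = 0, m_paired = log(0.5))
  dr_h <- simulate_fixed_effects(fit_h, S = 100, seed = 2)
  rci <- rci_from_draws(dr_h, fit_h, "NZ", "NZ(SP)")
  expect_equal(rci$values, rep(0.5, 100))
  expect_equal(rci$index_label, "NZ(SP)")
  expect_equal(rci$S, 100)

  expect_error(rci_from_draws(dr_h, fit_h, "NZ", "NZ(UK)"), "available",
               class = "rcindex_invalid_input")
})

test_that("draw-mean RCI matches the plug-in value for small variances", {
  V <- diag(c(1e-4, 1e-4, 0))
  fit <- toy_fit(m_single = log(0.04), m_paired = log(0.04) + log1p(-0.35),
                 vcov = V)
  dr <- simulate_fixed_effects(fit, S = 20000, seed = 11)
  rci <- rci_from_draws(dr, fit, "NZ", "NZ(SP)")
  mc_se <- stats::sd(rci$values) / sqrt(rci$S)
  # second-order (Jensen) bias is ~ (1 - RCI) * sigma_d^2 = 1.3e-4 here
  expect_lt(abs(mean(rci$values) - 0.35), 3 * mc_se + 2e-4)
})

test_that("summaries use equal-tailed nested quantile intervals", {
  s_const <- summarize_rci(structure(list(index_label = "x", values = rep(0.2, 1000),
                                          S = 1000, species = NA, soil_country = NA),
                                     class = "rci_draws"))
  expect_equal(s_const$mean, 0.2)
  expect_equal(unname(s_const$ci50), c(0.2, 0.2))
  expect_equal(unname(s_const$ci95), c(0.2, 0.2))

  set.seed(3)
  z <- rnorm(100000)
  s_norm <- summarize_rci(z)
  expect_equal(unname(s_norm$ci95), c(-1.96, 1.96), tolerance = 0.03 / 1.96)
  expect_equal(unname(s_norm$ci50), c(qnorm(0.25), qnorm(0.75)),
               tolerance = 0.03)

  # ci50 nested in ci95 for arbitrary draw sets
  set.seed(4)
  for (i in 1:20) {
    s <- summarize_rci(rnorm(500, sd = runif(1, 0.1, 2)))
    expect_lte(s$ci95[["lower"]], s$ci50[["lower"]])
    expect_lte(s$ci50[["lower"]], s$ci50[["upper"]])
    expect_lte(s$ci50[["upper"]], s$ci95[["upper"]])
  }
  expect_error(summarize_rci(numeric(0)), class = "rcindex_invalid_input")
})

test_that("RCI differences follow the sign convention and significance rule", {
  mk <- function(values, label = "NZ(SP)") {
    structure(list(index_label = label, values = values, S = length(values),
                   seed = NULL, species = "arvense", soil_country = "NZ"),
              class = "rci_draws")
  }
  # identical draws: mean 0, not significant
  same <- rci_difference(mk(seq(0, 1, length.out = 1000)),
                         mk(seq(0, 1, length.out = 1000), "SP(NZ)"))
  expect_equal(same$mean_diff, 0)
  expect_false(same$significant)

  # introduced 0.6, native 0.2: +0.4, native more competitive, significant
  d <- rci_difference(mk(rep(0.6, 1000)), mk(rep(0.2, 1000), "SP(NZ)"))
  expect_equal(d$mean_diff, 0.4)
  expect_true(d$significant)
  expect_equal(d$native_partner, "SP")

  expect_error(rci_difference(mk(rep(0, 10)), mk(rep(0, 11), "SP(NZ)")),
               class = "rcindex_invalid_input")
})

test_that("common random numbers shrink the variance of the difference", {
  # strongly correlated paired cells induce correlated RCI draws
  V <- matrix(0.002, 5, 5) + diag(rep(0.002, 5))
  V[2, 4] <- V[4, 2] <- 0.0038  # corr(m_NZ(SP), m_SP(NZ)) ~ 0.95
  b <- c(log(0.04), log(0.03), log(0.045), log(0.035), 0.1)
  names(b) <- c("NZ", "NZ(SP)", "SP", "SP(NZ)", "nodulation")
  fit <- growth_fit(c("NZ", "NZ(SP)", "SP", "SP(NZ)"), b, V,
                    species = "arvense", soil_country = "SP")
  dr <- simulate_fixed_effects(fit, S = 50000, seed = 21)
  d_nz <- rci_from_draws(dr, fit, "NZ", "NZ(SP)")
  d_sp <- rci_from_draws(dr, fit, "SP", "SP(NZ)")
  paired_var <- var(d_nz$values - d_sp$values)
  set.seed(22)
  indep_var <- var(d_nz$values - sample(d_sp$values))
  expect_lt(paired_var, indep_var)
})

test_that("propagation is equivariant under cell relabelling", {
  V <- matrix(c(0.01, 0.002, 0, 0.002, 0.02, 0, 0, 0, 0.001), 3, 3)
  b <- c(log(0.05), log(0.03), 0.12)
  names(b) <- c("NZ", "NZ(SP)", "nodulation")
  fit <- growth_fit(c("NZ", "NZ(SP)"), b, V, species = "arvense",
                    soil_country = "SP")
  # permute the coefficient order; same cells, same seed -> same RCI values
  perm <- c(2, 1, 3)
  fit_p <- growth_fit(c("NZ(SP)", "NZ"), b[perm], V[perm, perm],
                      species = "arvense", soil_country = "SP")
  s1 <- summarize_rci(rci_from_draws(simulate_fixed_effects(fit, 20000, seed = 5),
                                     fit, "NZ", "NZ(SP)"))
  s2 <- summarize_rci(rci_from_draws(simulate_fixed_effects(fit_p, 20000, seed = 5),
                                     fit_p, "NZ", "NZ(SP)"))
  expect_equal(s1$mean, s2$mean, tolerance = 0.01)
  expect_equal(unname(s1$ci95), unname(s2$ci95), tolerance = 0.02)
})
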