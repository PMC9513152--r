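test_that("the just-identified one-factor model matches its closed form", {
  # With three indicators and one factor the ML solution is exact algebra:
  # phi = s12 s13 / s23, lam2 = s23 / s13, lam3 = s23 / s12,
  # theta_j = s_jj - lam_j^2 phi, and the fit is perfect.
  dat <- read.csv(fixture_path("onefactor"))
  S <- cov(dat)
  lam2 <- S[2, 3] / S[1, 3]
  lam3 <- S[2, 3] / S[1, 2]
  phi <- S[1, 2] * S[1, 3] / S[2, 3]
  theta <- diag(S) - c(1, lam2, lam3)^2 * phi
  fit <- iit_cfa(dat, fixture_models()$onefactor)
  expect_equal(unname(fit$estimates[c("f1=~y2", "f1=~y3")]), c(lam2, lam3),
               tolerance = 1e-6)
  expect_equal(unname(fit$estimates["phi_f1.f1"]), phi, tolerance = 1e-6)
  expect_equal(unname(fit$estimates[paste0("theta_y", 1:3)]),
               unname(theta), tolerance = 1e-6)
  expect_lt(fit$chisq, 1e-8)
  expect_equal(fit$df, 0)
  expect_true(is.na(fit$indices$cmin_df) && is.na(fit$indices$rmsea))
})

test_that("estimates, chi-square and indices match the frozen oracle", {
  for (name in names(oracle_fixtures)) {
    want <- oracle_fixtures[[name]]
    fit <- iit_cfa(read.csv(fixture_path(name)), fixture_models()[[name]])
    expect_true(fit$converged, label = paste(name, "converged"))
    expect_equal(fit$df, want$df)
    expect_lt(abs(fit$chisq - want$chisq), 1e-4)
    expect_lt(max(abs(fit$estimates - want$estimates)), 1e-4)
    expect_lt(max(abs(fit$se - want$se)), 1e-3)
    expect_lt(max(abs(fit$std$first_order - want$std_first)), 1e-4)
    for (nm in c("cmin_df", "gfi", "cfi", "tli", "rmsea", "srmr")) {
      if (is.na(want[[nm]])) expect_true(is.na(fit$indices[[nm]]))
      else expect_lt(abs(fit$indices[[nm]] - want[[nm]]), 1e-4)
    }
    expect_lt(abs(fit$baseline$chisq - want$chisq_baseline), 1e-6)
    expect_equal(fit$baseline$df, want$df_baseline)
    if (!is.null(want$std_second))
      expect_lt(max(abs(fit$std$second_order - want$std_second)), 1e-4)
  }
})

test_that("degrees of freedom bookkeeping holds for the shipped model", {
  m <- cfa_model()
  expect_equal(m$p, 13)
  expect_equal(m$n_free, 9 + 4 + 4 + 13)
  expect_equal(m$df, 91 - m$n_free)   # 61
})

test_that("fitting the same covariance twice is bit-identical", {
  dat <- read.csv(fixture_path("twofactor"))
  cs <- sample_covariance(dat)
  m <- fixture_models()$twofactor
  f1 <- iit_cfa(sample_cov = cs$S, sample_n = cs$N, model = m)
  f2 <- iit_cfa(sample_cov = cs$S, sample_n = cs$N, model = m)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$chisq, f2$chisq)
  expect_identical(f1$indices, f2$indices)
})

test_that("refitting data simulated from a fitted model shows near-perfect fit", {
  fit0 <- iit_cfa(read.csv(fixture_path("secondorder")),
                  fixture_models()$secondorder)
  y <- simulate(fit0, nsim = 5000, seed = 99)
  fit1 <- iit_cfa(y, fixture_models()$secondorder)
  expect_gte(fit1$indices$cfi, 0.99)
  expect_lte(fit1$indices$rmsea, 0.03)
  expect_lte(fit1$indices$srmr, 0.02)
})

test_that("standardized loadings of admissible fits lie in (-1, 1)", {
  for (name in names(oracle_fixtures)) {
    fit <- iit_cfa(read.csv(fixture_path(name)), fixture_models()[[name]])
    expect_true(all(abs(fit$std$first_order) < 1))
    if (!is.null(fit$std$second_order))
      expect_true(all(abs(fit$std$second_order) < 1))
  }
})

test_that("the sample-size guard and input validation fire", {
  m <- fixture_models()$onefactor
  expect_error(iit_cfa(read.csv(fixture_path("onefactor"))[1:6, ], m),
               "exceed the number of free parameters")
  expect_error(iit_cfa(data.frame(a = 1:10), m), "lacks indicator")
  expect_error(iit_cfa(model = m), "supply either")
})

test_that("estimates table carries fixed markers and Wald tests", {
  fit <- iit_cfa(read.csv(fixture_path("secondorder")),
                 fixture_models()$secondorder)
  tab <- fit$table
  markers <- tab$estimate[tab$indicator %in% c("y1", "y4", "y7") &
                            tab$factor != "overall"]
  expect_true(all(markers == 1))
  expect_true(all(is.na(tab$se[tab$indicator %in% c("y1", "y4", "y7") &
                                 tab$factor != "overall"])))
  free <- !is.na(tab$se)
  expect_equal(tab$z[free], tab$estimate[free] / tab$se[free])
  expect_true(all(tab$p_value[free] >= 0 & tab$p_value[free] <= 1))
})

test_that("factor-score prediction tracks the generating factors", {
  set.seed(5)
  sim <- simulate_scores(2000, standardized = TRUE, truncate = FALSE)
  fit <- iit_cfa(sim$scores)
  sc <- predict(fit, sim$scores)
  expect_equal(colnames(sc), c("progress", "quality", "regulation",
                               "scientificity", "overall"))
  expect_gt(cor(sc[, "overall"], sim$xi), 0.7)
  expect_gt(cor(sc[, "progress"], sim$eta[, "progress"]), 0.7)
})
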