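test_that("sample covariance uses denominator N-1 and is symmetric", {
  cs <- sample_covariance(rbind(c(0, 0), c(2, 2)))
  expect_equal(cs$S, matrix(2, 2, 2), ignore_attr = TRUE)
  expect_equal(cs$N, 2)

  set.seed(1)
  x <- matrix(rnorm(60), 20, 3)
  cs2 <- sample_covariance(x)
  expect_identical(cs2$S, t(cs2$S))
  expect_error(sample_covariance(cbind(x, const = 1)), "constant")
})

test_that("sample covariance converges to the generating covariance", {
  set.seed(2)
  Sig <- matrix(c(2, 1, 1, 2), 2)
  y <- matrix(rnorm(2e5), ncol = 2) %*% chol(Sig)
  cs <- sample_covariance(y)
  expect_lt(max(abs(cs$S - Sig)), 0.05)
})

test_that("listwise deletion drops incomplete rows with a message", {
  x <- matrix(rnorm(30), 10, 3)
  x[3, 2] <- NA
  expect_message(cs <- sample_covariance(x), "1 incomplete")
  expect_equal(cs$N, 9)
})

test_that("implied covariance follows the factor algebra", {
  # one factor, loadings (1, 1), factor variance 1, residuals I
  m <- cfa_model(list(f = c("y1", "y2")), second_order = FALSE)
  Sigma <- implied_covariance(m, c(1, 1, 1, 1))  # lam2, phi, theta1, theta2
  expect_equal(Sigma, matrix(c(2, 1, 1, 2), 2), ignore_attr = TRUE)

  # zero second-order loadings -> block-diagonal by factor
  m2 <- cfa_model(list(f1 = c("y1", "y2"), f2 = c("y3", "y4")),
                  second_order = TRUE)
  # par: lam free (2), gamma (2), psi (2), theta (4)
  Sigma2 <- implied_covariance(m2, c(0.8, 0.7, 0, 0, 1, 1, rep(0.5, 4)))
  expect_equal(Sigma2[1:2, 3:4], matrix(0, 2, 2), ignore_attr = TRUE)
  expect_gt(Sigma2[1, 2], 0)
})

test_that("the ML discrepancy matches its closed forms", {
  S <- diag(2); colnames(S) <- rownames(S) <- c("a", "b")
  expect_equal(ml_discrepancy(S, S), 0)
  expect_equal(ml_discrepancy(diag(c(2, 2)), diag(c(1, 1))), 2 - log(4))
  set.seed(3)
  for (i in 1:10) {
    A <- crossprod(matrix(rnorm(9), 3)) + diag(3)
    B <- crossprod(matrix(rnorm(9), 3)) + diag(3)
    expect_gte(ml_discrepancy(A, B), 0)
  }
  expect_error(ml_discrepancy(diag(2), matrix(1, 2, 2)), "singular")
})

test_that("the independence baseline has its closed-form chi-square", {
  expect_equal(baseline_chisq(diag(c(3, 5)), 50)$chisq, 0)
  # p = 2, r = 0.6, N = 101: chi2_B = -100 log(1 - 0.36)
  S <- matrix(c(1, 0.6, 0.6, 1), 2)
  b <- baseline_chisq(S, 101)
  expect_equal(b$chisq, -100 * log(0.64))
  expect_equal(b$df, 1)
  expect_equal(baseline_chisq(diag(13), 100)$df, 78)
})

test_that("fit indices match their closed forms", {
  S <- matrix(c(2, 0.8, 0.8, 1.5), 2)
  sat <- fit_indices(0, 0, 100, 1, S, S, 101)
  expect_equal(sat$gfi, 1)
  expect_equal(sat$cfi, 1)
  expect_equal(sat$srmr, 0)
  expect_true(is.na(sat$cmin_df) && is.na(sat$rmsea) && is.na(sat$tli))

  idx <- fit_indices(100, 50, 1050, 78, S, S, 101)
  expect_equal(idx$rmsea, sqrt(50 / 5000))     # 0.1
  expect_equal(idx$cmin_df, 2)

  idx2 <- fit_indices(150, 50, 1050, 78, S, S, 101)
  expect_equal(idx2$cfi, 1 - 100 / 972)
  expect_equal(idx2$tli, ((1050 / 78) - 3) / ((1050 / 78) - 1))
})

test_that("standardized loadings follow the variance-ratio algebra", {
  # marker loading 1, factor variance 1, residual 1 -> std = 1/sqrt(2)
  m <- cfa_model(list(f = c("y1", "y2")), second_order = FALSE)
  par <- c(1, 1, 1, 1)               # lam2, phi, theta1, theta2
  fit <- list(model = m, estimates = par,
              Sigma = implied_covariance(m, par))
  std <- standardized_solution(fit)
  expect_equal(unname(std$first_order["y1"]), 1 / sqrt(2))

  # already-standardized model: std equals the raw loading
  lam2 <- 0.6
  par3 <- c(lam2, 1, 0, 1 - lam2^2)  # unit implied variances
  fit3 <- list(model = m, estimates = par3,
               Sigma = implied_covariance(m, par3))
  std3 <- standardized_solution(fit3)
  expect_equal(unname(std3$first_order["y1"]), 1)
  expect_equal(unname(std3$first_order["y2"]), lam2)
})

test_that("chi-square and indices are invariant to rescaling an indicator", {
  dat <- read.csv(fixture_path("twofactor"))
  m <- fixture_models()$twofactor
  f1 <- iit_cfa(dat, m)
  dat2 <- dat
  dat2$y2 <- dat2$y2 * 7.3
  f2 <- iit_cfa(dat2, m)
  expect_lt(abs(f1$chisq - f2$chisq), 1e-6)
  for (nm in c("cfi", "tli", "rmsea", "srmr"))
    expect_lt(abs(f1$indices[[nm]] - f2$indices[[nm]]), 1e-6)
  # standardized solution identical too
  expect_lt(max(abs(f1$std$first_order - f2$std$first_order)), 1e-6)
})
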