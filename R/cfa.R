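#' Specify a confirmatory factor model
#'
#' Defines a CFA measurement structure: each indicator loads on exactly one
#' first-order factor, the first indicator listed for each factor is its
#' marker (loading fixed to 1), and, in the second-order form, the
#' first-order factors load on a single second-order factor whose variance
#' is fixed to 1 with all second-order loadings free. In the first-order
#' form the factor covariance matrix is unstructured (free variances and
#' covariances).
#'
#' The default is the shipped 13-indicator, 4-factor second-order structure
#' of the IIT quality instrument: the four attributes are the first-order
#' factors and overall quality the second-order factor.
#'
#' @param factors named list: factor name -> character vector of indicator
#'   ids, the first being the marker.
#' @param second_order logical; add the single second-order factor.
#' @return object of class `cfa_model`.
#' @examples
#' m <- cfa_model()            # the IIT validation structure
#' m$n_free                    # 30 free parameters, df = 91 - 30
#' @export
cfa_model <- function(factors = iit_factor_structure(), second_order = TRUE) {
  stopifnot(is.list(factors), length(factors) >= 1,
            !is.null(names(factors)))
  indicators <- unlist(factors, use.names = FALSE)
  if (anyDuplicated(indicators))
    stop("each indicator may load on exactly one factor")
  k <- length(factors)
  p <- length(indicators)
  if (second_order && k < 2)
    stop("a second-order factor needs at least two first-order factors")
  markers <- vapply(factors, `[`, character(1), 1)
  n_lambda <- p - k
  n_phi <- if (second_order) 2L * k else k * (k + 1L) / 2L
  n_free <- n_lambda + n_phi + p
  structure(list(factors = factors, indicator_ids = indicators,
                 factor_names = names(factors), markers = markers,
                 second_order = second_order,
                 p = p, k = k, n_free = n_free,
                 df = p * (p + 1L) / 2L - n_free),
            class = "cfa_model")
}

#' @rdname cfa_model
#' @export
iit_factor_structure <- function() {
  tab <- default_index_table()
  split(tab$id, factor(tab$attribute, levels = .iit_attributes))
}

#' @export
print.cfa_model <- function(x, ...) {
  cat(if (x$second_order) "Second-order" else "First-order",
      "CFA model:", x$p, "indicators,", x$k, "factors,",
      x$n_free, "free parameters (df =", paste0(x$df, ")\n"))
  for (f in x$factor_names)
    cat(sprintf("  %s =~ %s\n", f, paste(x$factors[[f]], collapse = " + ")))
  if (x$second_order)
    cat("  overall =~", paste(x$factor_names, collapse = " + "), "\n")
  invisible(x)
}

# --- parameter bookkeeping -------------------------------------------------
#
# Free parameters, on the natural (untransformed) scale, in fixed order:
#   second-order model: lambda (p-k non-marker loadings), gamma (k),
#                       psi (k first-order disturbance variances),
#                       theta (p residual variances)
#   first-order model:  lambda (p-k), vech(Phi) (k(k+1)/2, column-major
#                       lower triangle), theta (p)
# The optimizer works on a transformed scale where variances are log()ed
# and, for the first-order model, Phi is parameterized by its Cholesky
# factor with log()ed diagonal, so the implied covariance is positive
# definite everywhere on the search space.

par_names <- function(model) {
  free_load <- unlist(lapply(model$factor_names, function(f)
    paste0(f, "=~", setdiff(model$factors[[f]], model$markers[f]))))
  theta <- paste0("theta_", model$indicator_ids)
  if (model$second_order)
    c(free_load, paste0("overall=~", model$factor_names),
      paste0("psi_", model$factor_names), theta)
  else {
    ph <- outer(model$factor_names, model$factor_names,
                function(a, b) paste0("phi_", a, ".", b))
    c(free_load, ph[lower.tri(ph, diag = TRUE)], theta)
  }
}

# Natural-scale parameter vector -> model matrices.
cfa_matrices <- function(model, par) {
  p <- model$p; k <- model$k
  Lambda <- matrix(0, p, k, dimnames = list(model$indicator_ids,
                                            model$factor_names))
  i <- 0L
  for (f in seq_len(k)) {
    ids <- model$factors[[f]]
    Lambda[ids[1], f] <- 1
    for (id in ids[-1]) {
      i <- i + 1L
      Lambda[id, f] <- par[i]
    }
  }
  if (model$second_order) {
    gamma <- par[i + seq_len(k)]; i <- i + k
    psi <- par[i + seq_len(k)]; i <- i + k
    Phi <- tcrossprod(gamma) + diag(psi, k)
  } else {
    gamma <- NULL; psi <- NULL
    Phi <- matrix(0, k, k)
    Phi[lower.tri(Phi, diag = TRUE)] <- par[i + seq_len(k * (k + 1) / 2)]
    i <- i + k * (k + 1) / 2
    Phi <- Phi + t(Phi) - diag(diag(Phi), k)
  }
  theta <- par[i + seq_len(p)]
  list(Lambda = Lambda, Phi = Phi, theta = theta,
       gamma = gamma, psi = psi)
}

# transformed (optimizer) scale <-> natural scale
par_untransform <- function(model, tpar) {
  p <- model$p; k <- model$k; nl <- p - k
  lam <- tpar[seq_len(nl)]
  if (model$second_order) {
    gamma <- tpar[nl + seq_len(k)]
    psi <- exp(tpar[nl + k + seq_len(k)])
    theta <- exp(tpar[nl + 2 * k + seq_len(p)])
    c(lam, gamma, psi, theta)
  } else {
    nc <- k * (k + 1) / 2
    L <- matrix(0, k, k)
    L[lower.tri(L, diag = TRUE)] <- tpar[nl + seq_len(nc)]
    diag(L) <- exp(diag(L))
    Phi <- tcrossprod(L)
    theta <- exp(tpar[nl + nc + seq_len(p)])
    c(lam, Phi[lower.tri(Phi, diag = TRUE)], theta)
  }
}

par_start <- function(model, S) {
  p <- model$p; k <- model$k
  lam <- rep(1, p - k)
  theta <- log(pmax(0.5 * diag(S)[model$indicator_ids], 1e-4))
  if (model$second_order) {
    c(lam, rep(0.7, k), rep(log(0.5), k), theta)
  } else {
    L <- diag(sqrt(pmax(0.5 * diag(S)[model$markers], 1e-4)), k)
    tL <- L; diag(tL) <- log(diag(L))
    c(lam, tL[lower.tri(tL, diag = TRUE)], theta)
  }
}

# --- covariance algebra ----------------------------------------------------

#' Model-implied covariance matrix
#'
#' For the second-order model, `Sigma = Lambda (gamma gamma' + Psi) Lambda'
#' + Theta` with the second-order factor variance fixed at 1; for the
#' first-order model `Sigma = Lambda Phi Lambda' + Theta`.
#'
#' @param model a [cfa_model()]
#' @param par free-parameter vector on the natural scale (see
#'   [coef.iit_cfa()] for the ordering)
#' @return p x p implied covariance matrix
#' @export
implied_covariance <- function(model, par) {
  m <- cfa_matrices(model, par)
  Sigma <- m$Lambda %*% m$Phi %*% t(m$Lambda) + diag(m$theta, model$p)
  dimnames(Sigma) <- list(model$indicator_ids, model$indicator_ids)
  (Sigma + t(Sigma)) / 2
}

#' Maximum-likelihood discrepancy between two covariance matrices
#'
#' `F_ML = log|Sigma| - log|S| + tr(S Sigma^-1) - p`; nonnegative, and zero
#' iff `S == Sigma`.
#'
#' @param S sample covariance (positive definite)
#' @param Sigma implied covariance (positive definite)
#' @return nonnegative scalar
#' @export
ml_discrepancy <- function(S, Sigma) {
  p <- nrow(S)
  cS <- tryCatch(chol(S), error = function(e) NULL)
  cZ <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(cS) || is.null(cZ))
    stop(sprintf(
      "singular covariance matrix (condition numbers: S %.3g, Sigma %.3g)",
      kappa(S), kappa(Sigma)))
  ldS <- 2 * sum(log(diag(cS)))
  ldZ <- 2 * sum(log(diag(cZ)))
  Zinv <- chol2inv(cZ)
  ldZ - ldS + sum(S * Zinv) - p
}

#' Sample covariance summary of a score matrix
#'
#' Complete rows only (listwise deletion, with a message when rows are
#' dropped); denominator `N - 1`.
#'
#' @param data n x p numeric matrix or data.frame of indicator scores
#' @return list of class `cov_summary` with `S`, `N`, `p`
#' @export
sample_covariance <- function(data) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("indicator scores must be numeric")
  cc <- stats::complete.cases(data)
  if (!all(cc))
    message("dropping ", sum(!cc), " incomplete row(s) (listwise deletion)")
  data <- data[cc, , drop = FALSE]
  if (nrow(data) < 2) stop("need at least 2 complete rows")
  S <- stats::cov(data)
  if (any(diag(S) <= 0))
    stop("constant column(s): ",
         paste(colnames(data)[diag(S) <= 0], collapse = ", "))
  structure(list(S = (S + t(S)) / 2, N = nrow(data), p = ncol(data)),
            class = "cov_summary")
}

#' Chi-square of the independence baseline model
#'
#' The baseline constrains all covariances to zero (`Sigma_B = diag(S)`), so
#' its minimized discrepancy is `-log|R|` with `R` the sample correlation
#' matrix, `chi2_B = (N - 1) * F_B`, `df_B = p(p-1)/2`.
#'
#' @param S sample covariance
#' @param N sample size
#' @return list with `chisq`, `df`, `fmin`
#' @export
baseline_chisq <- function(S, N) {
  R <- stats::cov2cor(S)
  f <- -determinant(R, logarithm = TRUE)$modulus[1]
  p <- nrow(S)
  list(chisq = (N - 1) * f, df = p * (p - 1) / 2, fmin = f)
}

#' Fit indices from model and baseline chi-squares
#'
#' Implements the conventional formulas: CMIN/DF; the Joreskog-Sorbom
#' ML-based GFI `1 - tr[(Sigma^-1 S - I)^2] / tr[(Sigma^-1 S)^2]`; CFI and
#' TLI against the independence baseline; `RMSEA =
#' sqrt(max(chi2 - df, 0) / (df (N-1)))`; and SRMR over correlation-metric
#' residuals including the diagonal, denominator `p(p+1)/2`. With `df = 0`
#' (saturated model) CMIN/DF, TLI and RMSEA are undefined and returned as
#' `NA`.
#'
#' @param chisq,df model chi-square and degrees of freedom
#' @param chisq_b,df_b baseline chi-square and degrees of freedom
#' @param S,Sigma sample and implied covariance
#' @param N sample size
#' @return named list: `cmin_df`, `gfi`, `cfi`, `tli`, `rmsea`, `srmr`
#' @export
fit_indices <- function(chisq, df, chisq_b, df_b, S, Sigma, N) {
  p <- nrow(S)
  W <- solve(Sigma, S)
  gfi <- 1 - sum(diag((W - diag(p)) %*% (W - diag(p)))) / sum(diag(W %*% W))
  num <- max(chisq - df, 0)
  den <- max(chisq_b - df_b, chisq - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  d <- sqrt(outer(diag(S), diag(S)))
  res <- (S - Sigma) / d
  srmr <- sqrt(sum(res[lower.tri(res, diag = TRUE)]^2) / (p * (p + 1) / 2))
  if (df > 0) {
    cmin_df <- chisq / df
    rmsea <- sqrt(max(chisq - df, 0) / (df * (N - 1)))
    tli <- ((chisq_b / df_b) - (chisq / df)) / ((chisq_b / df_b) - 1)
  } else {
    cmin_df <- NA_real_; rmsea <- NA_real_; tli <- NA_real_
  }
  list(cmin_df = cmin_df, gfi = gfi, cfi = cfi, tli = tli,
       rmsea = rmsea, srmr = srmr)
}

# Gradient of F_ML on the transformed scale.  With
# A = Sigma^-1 - Sigma^-1 S Sigma^-1:
#   dF/dlambda_jf = 2 (A Lambda Phi)[j, f]
#   dF/dPhi       = Lambda' A Lambda  (summed over the symmetric pair)
#   dF/dtheta_j   = A[j, j]
# then chained through gamma/psi (or the Cholesky factor) and the log
# transforms.
fml_grad_t <- function(model, tpar, S) {
  par <- par_untransform(model, tpar)
  m <- cfa_matrices(model, par)
  p <- model$p; k <- model$k; nl <- p - k
  Sigma <- m$Lambda %*% m$Phi %*% t(m$Lambda) + diag(m$theta, p)
  cZ <- chol(Sigma)
  Zinv <- chol2inv(cZ)
  A <- Zinv - Zinv %*% S %*% Zinv
  ALP <- A %*% m$Lambda %*% m$Phi
  g_lam <- numeric(nl)
  i <- 0L
  for (f in seq_len(k)) {
    ids <- model$factors[[f]][-1]
    for (id in ids) {
      i <- i + 1L
      g_lam[i] <- 2 * ALP[match(id, model$indicator_ids), f]
    }
  }
  B <- t(m$Lambda) %*% A %*% m$Lambda      # dF/dPhi (full symmetric form)
  g_theta <- diag(A) * m$theta             # chain through log
  if (model$second_order) {
    g_gamma <- 2 * as.vector(B %*% m$gamma)
    g_psi <- diag(B) * m$psi
    c(g_lam, g_gamma, g_psi, g_theta)
  } else {
    nc <- k * (k + 1) / 2
    L <- matrix(0, k, k)
    L[lower.tri(L, diag = TRUE)] <- tpar[nl + seq_len(nc)]
    diag(L) <- exp(diag(L))
    G <- 2 * B %*% L                       # dF/dL
    diag(G) <- diag(G) * diag(L)           # chain log-diagonal
    c(g_lam, G[lower.tri(G, diag = TRUE)], g_theta)
  }
}

#' Fit a confirmatory factor model by maximum likelihood
#'
#' Minimizes the ML discrepancy between the sample covariance of the
#' indicator scores and the model-implied covariance, using analytic
#' gradients and a quasi-Newton optimizer on a log-variance parameterization
#' that keeps the implied covariance positive definite throughout. The model
#' chi-square is `(N - 1) * F_ML` at the optimum; standard errors come from
#' the inverse numerical Hessian of the discrepancy on the natural parameter
#' scale (`vcov = 2/(N-1) H^-1`).
#'
#' @param data n x p matrix or data.frame holding the indicator columns
#'   named in the model (extra columns ignored). Alternatively pass
#'   `sample_cov` and `sample_n`.
#' @param model a [cfa_model()]; defaults to the IIT second-order structure.
#' @param sample_cov,sample_n covariance-input form: a p x p sample
#'   covariance with matching dimnames and the N it was computed from.
#' @param control list: `maxit` (default 500), `reltol` (default 1e-12),
#'   `grad_tol` for the convergence check (default 1e-6).
#' @return object of class `iit_cfa`; see [summary.iit_cfa()]. Components
#'   include `estimates` (natural-scale free parameters), `se`, `table`
#'   (estimates table with z and p values), `std` (standardized solution),
#'   `Sigma`, `fmin`, `chisq`, `df`, `baseline`, `indices`, `converged`,
#'   `grad_norm`, `heywood`.
#' @examples
#' sim <- simulate_scores(500, seed = 1, truncate = FALSE, standardized = TRUE)
#' fit <- iit_cfa(sim$scores)
#' fit
#' @export
iit_cfa <- function(data = NULL, model = cfa_model(), sample_cov = NULL,
                    sample_n = NULL, control = list()) {
  ctrl <- utils::modifyList(
    list(maxit = 500, reltol = 1e-12, grad_tol = 1e-6), control)
  if (is.null(sample_cov)) {
    if (is.null(data)) stop("supply either data or sample_cov + sample_n")
    data <- as.data.frame(data)
    missing_ix <- setdiff(model$indicator_ids, names(data))
    if (length(missing_ix))
      stop("data lacks indicator column(s): ",
           paste(missing_ix, collapse = ", "))
    cs <- sample_covariance(data[, model$indicator_ids, drop = FALSE])
  } else {
    stopifnot(!is.null(sample_n), nrow(sample_cov) == ncol(sample_cov))
    if (is.null(dimnames(sample_cov)))
      dimnames(sample_cov) <- list(model$indicator_ids, model$indicator_ids)
    cs <- structure(list(S = sample_cov[model$indicator_ids,
                                        model$indicator_ids],
                         N = sample_n, p = model$p),
                    class = "cov_summary")
  }
  S <- cs$S; N <- cs$N
  if (N <= model$n_free)
    stop("sample size (", N, ") must exceed the number of free parameters (",
         model$n_free, ")")
  fn <- function(tp) {
    Sigma <- implied_covariance(model, par_untransform(model, tp))
    tryCatch(ml_discrepancy(S, Sigma), error = function(e) 1e10)
  }
  gr <- function(tp) fml_grad_t(model, tp, S)
  tp0 <- par_start(model, S)
  opt <- stats::nlminb(tp0, fn, gr,
                       control = list(iter.max = ctrl$maxit,
                                      eval.max = 4 * ctrl$maxit,
                                      rel.tol = ctrl$reltol))
  # quasi-Newton polish to drive the gradient down further
  opt2 <- stats::optim(opt$par, fn, gr, method = "BFGS",
                       control = list(maxit = ctrl$maxit,
                                      reltol = ctrl$reltol))
  tp <- if (opt2$value <= opt$objective) opt2$par else opt$par
  grad_norm <- max(abs(gr(tp)))
  converged <- is.finite(grad_norm) && grad_norm < ctrl$grad_tol
  par <- par_untransform(model, tp)
  names(par) <- par_names(model)
  Sigma <- implied_covariance(model, par)
  fmin <- ml_discrepancy(S, Sigma)
  if (!converged)
    warning(sprintf(
      "optimizer did not reach gradient tolerance (max |grad| = %.3g)",
      grad_norm))
  # observed-information standard errors on the natural scale
  fn_nat <- function(q) {
    Sg <- implied_covariance(model, q)
    tryCatch(ml_discrepancy(S, Sg), error = function(e) 1e10)
  }
  H <- tryCatch(stats::optimHess(par, fn_nat), error = function(e) NULL)
  V <- if (!is.null(H))
    tryCatch(2 / (N - 1) * solve(H), error = function(e) NULL) else NULL
  se <- if (!is.null(V)) {
    v <- diag(V)
    ifelse(v > 0, sqrt(pmax(v, 0)), NA_real_)
  } else rep(NA_real_, length(par))
  names(se) <- names(par)
  m <- cfa_matrices(model, par)
  heywood <- any(m$theta < 1e-3 * diag(S)[model$indicator_ids]) ||
    (model$second_order && any(m$psi < 1e-4))
  base <- baseline_chisq(S, N)
  chisq <- (N - 1) * fmin
  df <- model$df
  idx <- fit_indices(chisq, df, base$chisq, base$df, S, Sigma, N)
  fit <- structure(
    list(model = model, S = S, N = N, estimates = par, se = se,
         vcov = V, Sigma = Sigma, fmin = fmin, chisq = chisq, df = df,
         baseline = base, indices = idx, converged = converged,
         grad_norm = grad_norm, heywood = heywood,
         means = if (!is.null(data)) colMeans(as.matrix(
           data[stats::complete.cases(data[, model$indicator_ids]),
                model$indicator_ids, drop = FALSE])) else NULL),
    class = "iit_cfa")
  fit$std <- standardized_solution(fit)
  fit$table <- estimates_table(fit)
  fit
}

#' Standardized solution of a fitted CFA
#'
#' Rescales each loading by the ratio of its factor's implied standard
#' deviation to its indicator's implied standard deviation; second-order
#' loadings by the second-order factor SD (fixed at 1) over the first-order
#' factor SD. Standardized loadings of a correctly specified model lie in
#' (-1, 1).
#'
#' @param fit an [iit_cfa()] fit
#' @return list with `first_order` (named by indicator), `second_order`
#'   (named by factor; `NULL` for first-order models), and
#'   `residual_std` (standardized residual variances `theta_j / Sigma_jj`).
#' @export
standardized_solution <- function(fit) {
  model <- fit$model
  m <- cfa_matrices(model, fit$estimates)
  sd_f <- sqrt(diag(m$Phi))
  sd_y <- sqrt(diag(fit$Sigma))
  fac_of <- rep(seq_len(model$k),
                vapply(model$factors, length, integer(1)))
  lam <- rowSums(m$Lambda)                       # one loading per indicator
  first <- lam * sd_f[fac_of] / sd_y[model$indicator_ids]
  names(first) <- model$indicator_ids
  second <- if (model$second_order) {
    stats::setNames(m$gamma / sd_f, model$factor_names)
  } else NULL
  list(first_order = first, second_order = second,
       residual_std = stats::setNames(
         m$theta / diag(fit$Sigma), model$indicator_ids))
}

# Estimates table mirroring a published CFA loading table: unstandardized
# estimate, standardized load, SE, Wald z, two-sided p (markers: fixed).
estimates_table <- function(fit) {
  model <- fit$model
  rows <- list()
  for (f in model$factor_names) {
    for (id in model$factors[[f]]) {
      fixed <- id == model$markers[f]
      nm <- paste0(f, "=~", id)
      est <- if (fixed) 1 else unname(fit$estimates[nm])
      se <- if (fixed) NA_real_ else unname(fit$se[nm])
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = nm, factor = f, indicator = id,
        estimate = est, std_load = unname(fit$std$first_order[id]),
        se = se, stringsAsFactors = FALSE)
    }
  }
  if (model$second_order) {
    for (f in model$factor_names) {
      nm <- paste0("overall=~", f)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = nm, factor = "overall", indicator = f,
        estimate = unname(fit$estimates[nm]),
        std_load = unname(fit$std$second_order[f]),
        se = unname(fit$se[nm]), stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$z <- tab$estimate / tab$se
  tab$p_value <- 2 * stats::pnorm(-abs(tab$z))
  tab
}
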