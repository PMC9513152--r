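#' @export
print.iit_cfa <- function(x, digits = 3, ...) {
  cat(if (x$model$second_order) "Second-order" else "First-order",
      "CFA fit by maximum likelihood\n")
  cat(sprintf("  N = %d, %d indicators, %d factors\n",
              x$N, x$model$p, x$model$k))
  cat(sprintf("  chi-square = %.3f on %d df (CMIN/DF = %s)\n",
              x$chisq, x$df,
              if (is.na(x$indices$cmin_df)) "undefined" else
                sprintf("%.3f", x$indices$cmin_df)))
  with(x$indices, cat(sprintf(
    "  GFI = %.3f  CFI = %.3f  TLI = %s  RMSEA = %s  SRMR = %.3f\n",
    gfi, cfi,
    if (is.na(tli)) "NA" else sprintf("%.3f", tli),
    if (is.na(rmsea)) "NA" else sprintf("%.3f", rmsea), srmr)))
  if (!x$converged)
    cat("  WARNING: not converged (max |grad| =",
        format(x$grad_norm, digits = 3), ")\n")
  if (x$heywood)
    cat("  WARNING: Heywood case (variance at boundary)\n")
  invisible(x)
}

#' Summary of a fitted CFA
#'
#' Prints the estimates table (unstandardized estimate, standardized
#' loading, standard error, Wald z, two-sided p) and the six fit indices.
#'
#' @param object an [iit_cfa()] fit
#' @param ... unused
#' @export
summary.iit_cfa <- function(object, ...) {
  structure(list(fit = object), class = "summary.iit_cfa")
}

#' @export
print.summary.iit_cfa <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nLoadings:\n")
  tab <- fit$table
  tab$estimate <- sprintf("%7.3f", tab$estimate)
  tab$std_load <- sprintf("%6.3f", tab$std_load)
  tab$se <- ifelse(is.na(tab$se), "      ", sprintf("%6.3f", tab$se))
  tab$z <- ifelse(is.na(tab$z), "      ", sprintf("%6.3f", tab$z))
  tab$p_value <- ifelse(is.na(tab$p_value), "      ",
                        sprintf("%6.4f", tab$p_value))
  print(tab[, c("parameter", "estimate", "std_load", "se", "z", "p_value")],
        row.names = FALSE)
  invisible(x)
}

#' @export
coef.iit_cfa <- function(object, ...) object$estimates

#' @export
vcov.iit_cfa <- function(object, ...) object$vcov

#' @export
fitted.iit_cfa <- function(object, ...) object$Sigma

#' Correlation-metric residuals of a fitted CFA
#'
#' `(s_ij - sigma_ij) / sqrt(s_ii s_jj)`; the root mean square of its lower
#' triangle (diagonal included) is the SRMR.
#'
#' @param object an [iit_cfa()] fit
#' @param ... unused
#' @export
residuals.iit_cfa <- function(object, ...) {
  d <- sqrt(outer(diag(object$S), diag(object$S)))
  (object$S - object$Sigma) / d
}

#' Factor scores for new observations
#'
#' Regression-method factor scores: `E[eta | y] = Phi Lambda' Sigma^-1 (y -
#' mu)`, with `mu` the indicator means of the fitting data (0 if the fit was
#' given a covariance only). For second-order models a column `overall` with
#' the second-order factor score is appended (`cov(xi, y) = Lambda gamma`).
#'
#' @param object an [iit_cfa()] fit
#' @param newdata matrix/data.frame with the indicator columns
#' @param ... unused
#' @return n x k (or k+1) matrix of factor scores
#' @export
predict.iit_cfa <- function(object, newdata, ...) {
  model <- object$model
  y <- as.matrix(as.data.frame(newdata)[, model$indicator_ids, drop = FALSE])
  mu <- if (!is.null(object$means)) object$means else
    stats::setNames(rep(0, model$p), model$indicator_ids)
  yc <- sweep(y, 2, mu[model$indicator_ids])
  m <- cfa_matrices(model, object$estimates)
  Zinv <- chol2inv(chol(object$Sigma))
  scores <- yc %*% t(m$Phi %*% t(m$Lambda) %*% Zinv)
  colnames(scores) <- model$factor_names
  if (model$second_order) {
    w <- Zinv %*% (m$Lambda %*% m$gamma)     # cov(xi, y) = Lambda gamma
    scores <- cbind(scores, overall = as.vector(yc %*% w))
  }
  scores
}

#' Simulate indicator data from a fitted CFA
#'
#' Draws multivariate normal samples with the fitted implied covariance (and
#' the fitting data's indicator means, if available). Used for
#' self-consistency checks: refitting data simulated from a fitted model
#' should show near-perfect fit indices.
#'
#' @param object an [iit_cfa()] fit
#' @param nsim number of rows to draw
#' @param seed optional seed
#' @param ... unused
#' @return nsim x p matrix with indicator columns
#' @export
simulate.iit_cfa <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$model$p
  z <- matrix(stats::rnorm(nsim * p), nsim, p)
  y <- z %*% chol(object$Sigma)
  if (!is.null(object$means)) y <- sweep(y, 2, object$means, `+`)
  colnames(y) <- object$model$indicator_ids
  y
}
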