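# Marginal logistic regression for clustered binary outcomes, fitted by
# generalised estimating equations with an exchangeable (or independence)
# working correlation, scale fixed at 1, and robust sandwich variance.

#' Fit a marginal logistic model by generalised estimating equations
#'
#' Population-averaged logistic regression for repeated binary outcomes
#' clustered by subject. Coefficients are updated by Fisher scoring on the
#' estimating equations `sum_i D_i' V_i^{-1} (y_i - mu_i) = 0` with working
#' covariance `V_i = A_i^{1/2} R(rho) A_i^{1/2}`, alternating with a moment
#' re-estimate of the exchangeable correlation from Pearson residuals
#' (`rho = sum over within-cluster pairs of e_j e_k / (N_pairs - p)`), until
#' the largest coefficient change is below `tol`. The scale parameter is
#' fixed at 1, as is standard for binary outcomes. Standard errors are
#' robust (sandwich) by default; the model-based covariance is also kept.
#'
#' With the independence working correlation and one observation per
#' cluster the fit coincides with ordinary logistic regression.
#'
#' @param formula Model formula with a binary (0/1 or logical) response.
#' @param data Data frame holding the response, covariates and cluster id.
#' @param id Cluster identifier: a vector of length `nrow(data)` or the
#'   name of a column of `data`.
#' @param corstr Working correlation: `"exchangeable"` or `"independence"`.
#' @param tol Convergence tolerance on the largest coefficient change.
#' @param maxit Maximum number of scoring iterations.
#' @return An object of class `gee_logit` with components `coefficients`,
#'   `vcov` (robust), `vcov_naive`, `rho`, `n_clusters`, `n_obs`, `niter`,
#'   `converged`, and the usual accessors ([coef()], [vcov()], [confint()],
#'   [summary()]). `summary()` reports odds ratios with Wald 95 %
#'   confidence intervals and p-values.
#' @examples
#' d <- data.frame(y = rbinom(40, 1, 0.5), x = rnorm(40), id = rep(1:20, 2))
#' fit <- gee_logit(y ~ x, d, id = "id")
#' summary(fit)
#' @export
gee_logit <- function(formula, data, id,
                      corstr = c("exchangeable", "independence"),
                      tol = 1e-6, maxit = 100) {
  corstr <- match.arg(corstr)
  if (is.character(id) && length(id) == 1) {
    if (!id %in% names(data)) stop("`id` column not found in `data`")
    id <- data[[id]]
  }
  stopifnot(length(id) == nrow(data))
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  if (is.logical(y)) y <- as.integer(y)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  keep <- stats::complete.cases(y, X, id)
  y <- y[keep]; X <- X[keep, , drop = FALSE]; id <- id[keep]
  if (!all(y %in% c(0, 1))) stop("response must be binary (0/1)")
  cl <- as.integer(factor(id))
  n_clusters <- max(cl)
  if (n_clusters < 2) stop("need at least 2 clusters")
  if (min(y) == max(y)) stop("outcome is degenerate (all 0 or all 1)")
  p <- ncol(X)
  n_i <- tabulate(cl)
  npairs <- sum(n_i * (n_i - 1)) / 2

  init <- stats::glm.fit(X, y, family = stats::binomial())
  beta <- init$coefficients
  if (any(!is.finite(beta)))
    stop("initial logistic fit failed (collinear design?)")

  rho <- 0
  rho_min <- -1 / (max(n_i) - 1) + 1e-6
  converged <- FALSE
  a <- 1; b_i <- rep(0, n_clusters)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    if (max(abs(eta)) > 30)
      stop("fitted probabilities numerically 0 or 1; possible separation")
    mu <- stats::plogis(eta)
    A <- mu * (1 - mu)
    s <- sqrt(A)
    e <- (y - mu) / s                       # Pearson residuals (scale 1)
    if (corstr == "exchangeable" && npairs > p) {
      se1 <- drop(rowsum(e, cl))
      se2 <- drop(rowsum(e^2, cl))
      rho <- sum((se1^2 - se2) / 2) / (npairs - p)
      rho <- min(max(rho, rho_min), 0.99)
    }
    U <- X * s                               # A^{1/2} X
    a <- 1 / (1 - rho)
    b_i <- -rho / ((1 - rho) * (1 + (n_i - 1) * rho))
    C <- rowsum(U, cl)
    sr <- drop(rowsum(e, cl))
    B <- a * crossprod(U) + crossprod(C, C * b_i)
    g <- a * crossprod(U, e) + crossprod(C, b_i * sr)
    delta <- solve(B, g)
    beta <- beta + drop(delta)
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  niter <- it

  # robust (sandwich) covariance at the final estimate
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  s <- sqrt(mu * (1 - mu))
  e <- (y - mu) / s
  U <- X * s
  C <- rowsum(U, cl)
  sr <- drop(rowsum(e, cl))
  B <- a * crossprod(U) + crossprod(C, C * b_i)
  Gmat <- a * rowsum(U * e, cl) + (b_i * sr) * C   # per-cluster scores
  Binv <- solve(B)
  vcov_rob <- Binv %*% crossprod(Gmat) %*% Binv
  dimnames(vcov_rob) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)

  structure(list(coefficients = beta, vcov = vcov_rob, vcov_naive = Binv,
                 rho = if (corstr == "exchangeable") rho else 0,
                 corstr = corstr, n_clusters = n_clusters,
                 n_obs = length(y), niter = niter, converged = converged,
                 formula = formula, call = match.call()),
            class = "gee_logit")
}

#' @export
coef.gee_logit <- function(object, ...) object$coefficients

#' @export
vcov.gee_logit <- function(object, ...) object$vcov

#' @export
confint.gee_logit <- function(object, parm, level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$coefficients
  out <- cbind(est - z * se, est + z * se)
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                              1 - (1 - level) / 2))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
print.gee_logit <- function(x, ...) {
  cat(sprintf("Marginal logistic model (GEE, %s working correlation)\n",
              x$corstr))
  cat(sprintf("%d observations in %d clusters; rho = %.4f; %s in %d iterations\n",
              x$n_obs, x$n_clusters, x$rho,
              if (x$converged) "converged" else "NOT converged", x$niter))
  print(x$coefficients)
  invisible(x)
}

#' @export
summary.gee_logit <- function(object, level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  pval <- 2 * stats::pnorm(-abs(z))
  qz <- stats::qnorm(1 - (1 - level) / 2)
  tab <- data.frame(estimate = object$coefficients, robust_se = se,
                    odds_ratio = exp(object$coefficients),
                    ci_lower = exp(object$coefficients - qz * se),
                    ci_upper = exp(object$coefficients + qz * se),
                    z = z, p_value = pval)
  out <- list(table = tab, rho = object$rho, corstr = object$corstr,
              n_clusters = object$n_clusters, n_obs = object$n_obs,
              converged = object$converged, level = level)
  class(out) <- "summary.gee_logit"
  out
}

#' @export
print.summary.gee_logit <- function(x, ...) {
  cat(sprintf("GEE marginal logistic model (%s; rho = %.4f)\n",
              x$corstr, x$rho))
  cat(sprintf("%d observations, %d clusters%s\n", x$n_obs, x$n_clusters,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(format(x$table, digits = 4))
  invisible(x)
}

#' Odds-ratio table of a fitted GEE model
#'
#' Convenience extractor: one row per model term with the exponentiated
#' coefficient, Wald 95 % confidence interval and p-value, the form in
#' which marginal logistic results are usually reported.
#'
#' @param object A [gee_logit()] fit.
#' @param level Confidence level.
#' @return Data frame with columns `term`, `odds_ratio`, `ci_lower`,
#'   `ci_upper`, `p_value`.
#' @export
odds_ratios <- function(object, level = 0.95) {
  stopifnot(inherits(object, "gee_logit"))
  tab <- summary(object, level = level)$table
  data.frame(term = rownames(tab), odds_ratio = tab$odds_ratio,
             ci_lower = tab$ci_lower, ci_upper = tab$ci_upper,
             p_value = tab$p_value, row.names = NULL)
}
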