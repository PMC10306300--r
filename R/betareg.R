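# Maximum-likelihood beta regression with a logit mean link and constant
# precision phi, for outcomes in (0,1) such as immune-cell cluster
# relative frequencies. Parametrization: y ~ Beta(mu*phi, (1-mu)*phi),
# logit(mu) = X beta.

.betareg_loglik <- function(par, X, y) {
  beta <- par[-length(par)]
  phi <- exp(par[length(par)])
  mu <- plogis(drop(X %*% beta))
  a <- mu * phi
  b <- (1 - mu) * phi
  sum(lgamma(phi) - lgamma(a) - lgamma(b) +
        (a - 1) * log(y) + (b - 1) * log1p(-y))
}

.betareg_grad <- function(par, X, y) {
  beta <- par[-length(par)]
  phi <- exp(par[length(par)])
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  ystar <- log(y) - log1p(-y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  gbeta <- phi * drop(crossprod(X, (ystar - mustar) * mu * (1 - mu)))
  dphi <- sum(digamma(phi) - mu * digamma(mu * phi) -
                (1 - mu) * digamma((1 - mu) * phi) +
                mu * log(y) + (1 - mu) * log1p(-y))
  c(gbeta, phi * dphi)   # chain rule for log-phi parametrization
}

#' Fit a beta regression by maximum likelihood
#'
#' Fits `y ~ Beta(mu*phi, (1-mu)*phi)` with `logit(mu) = X beta` and a
#' constant precision `phi` by quasi-Newton maximization of the exact
#' likelihood with analytic gradients. Starting values come from OLS on
#' `logit(y)`; standard errors from the observed information at the
#' optimum; Wald p-values per coefficient. Outcomes must lie strictly
#' inside (0, 1); with `boundary_correction = TRUE` exact 0/1 values are
#' first shrunk by the Smithson-Verkuilen transform
#' `y' = (y*(n-1) + 0.5)/n`.
#'
#' @param y Numeric response in (0, 1) (or \[0, 1\] with
#'   `boundary_correction`).
#' @param design Numeric design matrix including an intercept column, or a
#'   data frame passed to [stats::model.matrix()] with all columns as
#'   predictors.
#' @param boundary_correction Apply the Smithson-Verkuilen transform.
#' @param maxit Maximum optimizer iterations.
#' @return A `betareg_fit`: coefficients (logit scale), `phi`, standard
#'   errors, Wald p, log-likelihood, convergence flag and iteration count.
#'   Supports [tidy()] and [glance()].
#' @export
fit_beta_regression <- function(y, design, boundary_correction = FALSE,
                                maxit = 200L) {
  if (is.data.frame(design)) {
    design <- model.matrix(~ ., data = design)
  }
  if (is.null(dim(design))) design <- cbind(`(Intercept)` = 1, x = design)
  if (!is.matrix(design)) abort("`design` must be a matrix or data frame")
  if (length(y) != nrow(design)) abort("length(y) must match nrow(design)")
  ok <- is.finite(y) & stats::complete.cases(design)
  y <- y[ok]; X <- design[ok, , drop = FALSE]
  n <- length(y)
  if (any(y < 0 | y > 1)) abort("y outside [0, 1]")
  if (boundary_correction) {
    y <- (y * (n - 1) + 0.5) / n
  }
  if (any(y <= 0 | y >= 1)) {
    abort("y contains boundary values 0/1; use boundary_correction = TRUE")
  }
  if (qr(X)$rank < ncol(X)) abort("design matrix is rank deficient")
  # Starting values: OLS on logit(y); phi from the residual variance.
  ly <- qlogis(y)
  ols <- lm.fit(X, ly)
  mu0 <- plogis(drop(X %*% ols$coefficients))
  s2 <- sum(ols$residuals^2) / max(1, n - ncol(X))
  phi0 <- max(1, mean(1 / (s2 * mu0 * (1 - mu0))) - 1)
  par0 <- c(ols$coefficients, log(phi0))
  opt <- optim(par0, fn = .betareg_loglik, gr = .betareg_grad, X = X, y = y,
               method = "BFGS",
               control = list(fnscale = -1, maxit = maxit, reltol = 1e-12))
  H <- optimHess(opt$par, fn = .betareg_loglik, gr = .betareg_grad, X = X, y = y)
  info <- -H
  cov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, length(opt$par), length(opt$par)))
  p <- ncol(X)
  se <- sqrt(diag(cov)[seq_len(p)])
  est <- opt$par[seq_len(p)]
  z <- est / se
  structure(list(
    coefficients = setNames(est, colnames(X)),
    se = setNames(se, colnames(X)),
    z = setNames(z, colnames(X)),
    p.value = setNames(2 * pnorm(-abs(z)), colnames(X)),
    phi = unname(exp(opt$par[p + 1L])),
    phi_se = unname(exp(opt$par[p + 1L]) * sqrt(diag(cov)[p + 1L])),
    logLik = opt$value,
    converged = opt$convergence == 0L,
    iterations = opt$counts[["function"]],
    nobs = n,
    fitted = plogis(drop(X %*% est))
  ), class = "betareg_fit")
}

#' @export
print.betareg_fit <- function(x, ...) {
  cat(sprintf("<betareg_fit> logLik %.3f, phi %.3f, %s (n = %d)\n",
              x$logLik, x$phi,
              if (x$converged) "converged" else "NOT converged", x$nobs))
  print(tidy(x))
  invisible(x)
}

#' @method tidy betareg_fit
#' @export
tidy.betareg_fit <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients),
         std.error = unname(x$se), statistic = unname(x$z),
         p.value = unname(x$p.value))
}

#' @method glance betareg_fit
#' @export
glance.betareg_fit <- function(x, ...) {
  tibble(phi = x$phi, logLik = x$logLik, converged = x$converged,
         iterations = x$iterations, nobs = x$nobs)
}
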