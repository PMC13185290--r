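#' Beta-binomial density (mean / intra-class correlation parameterization)
#'
#' The beta-binomial distribution with mean `mu` and intra-class correlation
#' `rho` has beta shape parameters `a = mu (1 - rho) / rho` and
#' `b = (1 - mu) (1 - rho) / rho`; `rho -> 0` recovers the binomial.
#'
#' @param k Successes (reference-allele UMIs).
#' @param n Trials (phased UMIs).
#' @param mu Mean success probability in (0, 1).
#' @param rho Intra-class correlation in `[0, 1)`.
#' @param log Return log density.
#' @return Density values, vectorized over the arguments.
#' @export
dbetabinom <- function(k, n, mu, rho, log = FALSE) {
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  if (all(rho < 1e-10)) {
    ll <- stats::dbinom(k, n, mu, log = TRUE)
  } else {
    a <- mu * (1 - rho) / rho
    b <- (1 - mu) * (1 - rho) / rho
    ll <- lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
  }
  if (log) ll else exp(ll)
}

# random beta-binomial draws
rbetabinom <- function(n_draws, size, mu, rho) {
  mu <- rep_len(mu, n_draws)
  size <- rep_len(size, n_draws)
  if (rho < 1e-10) return(stats::rbinom(n_draws, size, mu))
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  p <- stats::rbeta(n_draws, a, b)
  stats::rbinom(n_draws, size, p)
}

#' Beta-binomial regression log-likelihood
#'
#' Mean model `logit(mu_i) = x_i' beta` with common intra-class correlation
#' `rho`; the log-likelihood is the sum of [dbetabinom()] log densities.
#'
#' @param beta Coefficient vector on the logit scale.
#' @param rho Intra-class correlation in `[0, 1)`.
#' @param k,n Successes and trials per observation.
#' @param X Design matrix (default: intercept only).
#' @return The log-likelihood value.
#' @export
betabinom_loglik <- function(beta, rho, k, n, X = NULL) {
  if (is.null(X)) X <- matrix(1, length(k), 1L)
  stopifnot(ncol(X) == length(beta), all(k >= 0), all(k <= n), all(n > 0))
  mu <- stats::plogis(drop(X %*% beta))
  sum(dbetabinom(k, n, mu, rho, log = TRUE))
}

bb_response <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  Y <- stats::model.response(mf)
  if (is.null(dim(Y)) || ncol(Y) != 2L)
    stop("the response must be a two-column matrix: cbind(ref, alt)")
  list(k = Y[, 1L], n = Y[, 1L] + Y[, 2L],
       X = stats::model.matrix(attr(mf, "terms"), mf))
}

new_bbfit <- function(coefficients, se, rho, vcov, logLik, converged,
                      boundary, method, k, n, X, call, sigma_b = NA_real_,
                      dispersion = NA_real_, fallback = FALSE,
                      df = NA_real_) {
  z <- coefficients / se
  p <- 2 * stats::pnorm(-abs(z))
  if (boundary || !converged) p[] <- NA_real_
  structure(list(coefficients = coefficients, se = se, z = z, p.values = p,
                 rho = rho, sigma_b = sigma_b, dispersion = dispersion,
                 vcov = vcov, logLik = logLik, converged = converged,
                 boundary = boundary, fallback = fallback, method = method,
                 k = k, n = n, X = X, nobs = length(k), df = df,
                 call = call),
            class = if (!is.na(sigma_b)) c("bbmixfit", "bbfit") else "bbfit")
}

# PORT reports benign termination states (X / relative convergence) with a
# nonzero code when started near the optimum
port_converged <- function(fit) {
  fit$convergence == 0L ||
    grepl("X-convergence|relative convergence", fit$message %||% "")
}

bb_neg_loglik <- function(par, k, n, X) {
  beta <- par[seq_len(ncol(X))]
  rho <- stats::plogis(par[ncol(X) + 1L])
  -betabinom_loglik(beta, rho, k, n, X)
}

# Core ML machinery shared by fit_betabinom and the testing loops.
# Assumes boundary/rank checks already done. Returns a bare list.
bb_ml_core <- function(k, n, X, start = NULL) {
  p <- ncol(X)
  if (is.null(start)) {
    if (p == 1L && all(X == 1)) {
      mu0 <- min(max(sum(k) / sum(n), 1e-3), 1 - 1e-3)
      start <- c(stats::qlogis(mu0), stats::qlogis(0.05))
    } else {
      g <- suppressWarnings(stats::glm.fit(X, cbind(k, n - k),
                                           family = stats::binomial()))
      start <- c(g$coefficients, stats::qlogis(0.05))
    }
  }
  # bounded rho transform: the likelihood flattens as rho -> 0 and PORT
  # (nlminb) handles an active bound cleanly where line searches abort
  lower <- c(rep(-Inf, p), stats::qlogis(1e-6))
  upper <- c(rep(Inf, p), stats::qlogis(0.99))
  start[p + 1L] <- min(max(start[p + 1L], lower[p + 1L]), upper[p + 1L])
  fit <- tryCatch(
    stats::nlminb(start, bb_neg_loglik, k = k, n = n, X = X,
                  lower = lower, upper = upper,
                  control = list(iter.max = 500, eval.max = 1000)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(beta = rep(NA_real_, p), se = rep(NA_real_, p),
                rho = NA_real_, vcov = matrix(NA_real_, p + 1, p + 1),
                logLik = NA_real_, converged = FALSE))
  rho_hat <- stats::plogis(fit$par[p + 1L])
  if (!port_converged(fit) && rho_hat < 1e-3) {
    # the likelihood is flat in rho near its boundary and the search can
    # stall descending toward it; the model there is the binomial limit,
    # whose ML fit is available in closed iterative form
    g <- suppressWarnings(stats::glm.fit(X, cbind(k, n - k),
                                         family = stats::binomial()))
    beta <- unname(g$coefficients)
    vc_b <- tryCatch(solve(crossprod(X, X * g$weights)),
                     error = function(e) matrix(NA_real_, p, p))
    vc <- matrix(NA_real_, p + 1L, p + 1L)
    vc[seq_len(p), seq_len(p)] <- vc_b
    se <- sqrt(pmax(diag(vc_b), 0))
    return(list(beta = beta, se = se, rho = 0, vcov = vc,
                logLik = betabinom_loglik(beta, 0, k, n, X),
                converged = g$converged && all(is.finite(se)) &&
                  all(se > 0)))
  }
  hess <- tryCatch(
    stats::optimHess(fit$par, bb_neg_loglik, k = k, n = n, X = X),
    error = function(e) matrix(NA_real_, p + 1L, p + 1L))
  fit$value <- fit$objective
  fit$hessian <- hess
  beta <- fit$par[seq_len(p)]
  rho <- stats::plogis(fit$par[p + 1L])
  vc <- tryCatch(solve(fit$hessian), error = function(e)
    matrix(NA_real_, p + 1L, p + 1L))
  se <- sqrt(pmax(diag(vc)[seq_len(p)], 0))
  if (!all(is.finite(se)) || !all(se > 0)) {
    # rho at its boundary flattens the likelihood in that direction and the
    # full observed information is singular; profile out rho instead
    vc_b <- tryCatch(solve(fit$hessian[seq_len(p), seq_len(p),
                                       drop = FALSE]),
                     error = function(e) NULL)
    if (!is.null(vc_b) && all(is.finite(vc_b))) {
      vc <- matrix(NA_real_, p + 1L, p + 1L)
      vc[seq_len(p), seq_len(p)] <- vc_b
      se <- sqrt(pmax(diag(vc_b), 0))
    }
  }
  list(beta = beta, se = se, rho = rho, vcov = vc, logLik = -fit$value,
       converged = port_converged(fit) && all(is.finite(se)) &&
         all(se > 0))
}

#' Fit a beta-binomial regression model
#'
#' Maximum-likelihood fit of the beta-binomial regression
#' `k_i ~ BetaBinomial(n_i, logistic(x_i' beta), rho)` by numerical
#' optimization on transformed parameters (`beta` free, `rho` through a logit
#' link). Wald standard errors and p-values come from the observed
#' information. With the default intercept-only design on oriented allele
#' counts, the intercept tests the null of balanced expression
#' (`logit(ref fraction) = 0`, i.e. 50:50).
#'
#' Degenerate data with all `k = 0` or all `k = n` sit on the likelihood
#' boundary: the fit is flagged and p-values are `NA`.
#'
#' @param formula Model formula with a two-column response, e.g.
#'   `cbind(ref_umis, alt_umis) ~ 1` or `~ condition`.
#' @param data A data.frame.
#' @param start Optional starting values `c(beta, qlogis(rho))`.
#' @return An object of class `bbfit` with `print`, `summary`, `coef`,
#'   `vcov`, `logLik`, `predict`, `simulate` and `residuals` methods.
#' @seealso [fit_quasibinom()], [fit_betabinom_mixed()]
#' @export
fit_betabinom <- function(formula, data, start = NULL) {
  r <- bb_response(formula, data)
  k <- r$k; n <- r$n; X <- r$X
  cl <- match.call()
  if (length(k) < 2L) stop("insufficient data: need at least 2 observations")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  p <- ncol(X)
  nm <- colnames(X)
  if (all(k == 0) || all(k == n)) {
    return(new_bbfit(stats::setNames(rep(NA_real_, p), nm),
                     stats::setNames(rep(NA_real_, p), nm), NA_real_,
                     matrix(NA_real_, p, p), NA_real_, FALSE, TRUE,
                     "betabinom", k, n, X, cl, df = p + 1))
  }
  fit <- bb_ml_core(k, n, X, start)
  new_bbfit(stats::setNames(fit$beta, nm), stats::setNames(fit$se, nm),
            fit$rho, fit$vcov[seq_len(p), seq_len(p), drop = FALSE],
            fit$logLik, fit$converged, FALSE, "betabinom", k, n, X, cl,
            df = p + 1)
}

#' Fit a quasi-binomial regression model
#'
#' Binomial GLM point estimates with Pearson-dispersion-scaled standard
#' errors and t-reference p-values — the standard overdispersion-robust
#' alternative to the beta-binomial fit.
#'
#' @inheritParams fit_betabinom
#' @return A `bbfit` object with `method = "quasibinom"` (its `rho` is `NA`;
#'   the estimated dispersion is in `$dispersion`).
#' @export
fit_quasibinom <- function(formula, data) {
  r <- bb_response(formula, data)
  k <- r$k; n <- r$n; X <- r$X
  cl <- match.call()
  if (length(k) < 2L) stop("insufficient data: need at least 2 observations")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  p <- ncol(X); nm <- colnames(X)
  if (all(k == 0) || all(k == n)) {
    return(new_bbfit(stats::setNames(rep(NA_real_, p), nm),
                     stats::setNames(rep(NA_real_, p), nm), NA_real_,
                     matrix(NA_real_, p, p), NA_real_, FALSE, TRUE,
                     "quasibinom", k, n, X, cl, df = p))
  }
  g <- suppressWarnings(stats::glm(formula, family = stats::quasibinomial(),
                                   data = data))
  sg <- summary(g)
  ct <- stats::coef(sg)
  out <- new_bbfit(stats::setNames(ct[, 1L], nm),
                   stats::setNames(ct[, 2L], nm), NA_real_,
                   stats::vcov(g), NA_real_, g$converged, FALSE,
                   "quasibinom", k, n, X, cl,
                   dispersion = sg$dispersion, df = p)
  # t-reference p-values (residual df), as reported by the GLM summary
  out$p.values[] <- ct[, 4L]
  out
}

# Laplace-approximated marginal log-likelihood for a per-sample random
# intercept. The inner modes for all samples are found simultaneously by a
# damped Newton iteration on the 1-D conditional log-densities, with
# finite-difference derivatives (all samples vectorized per iteration).
bb_mixed_marginal <- function(par, k, n, X, group, warm = NULL) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  rho <- stats::plogis(par[p + 1L])
  sigma <- exp(par[p + 2L])
  eta <- drop(X %*% beta)
  n_groups <- max(group)
  h <- 1e-4
  # per-group conditional log-density at offsets b (vector over groups)
  f_all <- function(b) {
    ll <- dbetabinom(k, n, stats::plogis(eta + b[group]), rho, log = TRUE)
    drop(rowsum(ll, group)) - b^2 / (2 * sigma^2) - log(sigma) -
      0.5 * log(2 * pi)
  }
  b <- if (!is.null(warm) && length(warm$b) == n_groups) warm$b else
    numeric(n_groups)
  for (it in 1:30) {
    f0 <- f_all(b); fp <- f_all(b + h); fm <- f_all(b - h)
    g1 <- (fp - fm) / (2 * h)
    g2 <- (fp - 2 * f0 + fm) / h^2
    bad <- !is.finite(g1) | !is.finite(g2) | g2 >= 0
    step <- ifelse(bad, 0, g1 / g2)
    step <- sign(step) * pmin(abs(step), 2)  # damp wild steps
    b <- b - step
    if (max(abs(step)) < 1e-8) break
  }
  f0 <- f_all(b); fp <- f_all(b + h); fm <- f_all(b - h)
  g2 <- (fp - 2 * f0 + fm) / h^2
  g2[!is.finite(g2) | g2 >= 0] <- -1e-8
  if (!is.null(warm)) warm$b <- b
  sum(f0 + 0.5 * log(2 * pi) - 0.5 * log(-g2))
}

#' Fit a beta-binomial mixed model
#'
#' Cell-level beta-binomial regression with a Gaussian random intercept per
#' sample of origin (standard deviation `sigma_b`), for testing allelic
#' imbalance on single-cell rows without pseudobulking. The random effect is
#' integrated out with a Laplace approximation per sample; fixed-effect Wald
#' p-values come from the observed information of the marginal likelihood.
#'
#' @inheritParams fit_betabinom
#' @param sample_col Name of the grouping column in `data` (default
#'   `"sample"`).
#' @return An object of class `bbmixfit` (inherits `bbfit`) with the extra
#'   element `sigma_b`.
#' @export
fit_betabinom_mixed <- function(formula, data, sample_col = "sample") {
  if (!sample_col %in% names(data))
    stop(sprintf("column '%s' not found", sample_col))
  r <- bb_response(formula, data)
  k <- r$k; n <- r$n; X <- r$X
  cl <- match.call()
  groups <- as.character(data[[sample_col]])
  if (length(unique(groups)) < 2L) {
    warning("single sample: falling back to fit_betabinom")
    out <- fit_betabinom(formula, data)
    out$fallback <- TRUE
    return(out)
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  p <- ncol(X); nm <- colnames(X)
  if (all(k == 0) || all(k == n)) {
    return(new_bbfit(stats::setNames(rep(NA_real_, p), nm),
                     stats::setNames(rep(NA_real_, p), nm), NA_real_,
                     matrix(NA_real_, p, p), NA_real_, FALSE, TRUE,
                     "mixed_bb", k, n, X, cl, sigma_b = 0, df = p + 2))
  }
  group_i <- as.integer(factor(groups))
  pooled <- fit_betabinom(formula, data)
  rho0 <- if (is.na(pooled$rho)) 0.05 else max(min(pooled$rho, 0.5), 1e-3)
  start <- c(if (pooled$converged && !anyNA(pooled$coefficients))
               pooled$coefficients else rep(0, p),
             stats::qlogis(rho0), log(0.3))
  warm <- new.env(parent = emptyenv())
  neg <- function(par) -bb_mixed_marginal(par, k, n, X, group_i, warm)
  lower <- c(rep(-Inf, p), stats::qlogis(1e-6), log(1e-3))
  upper <- c(rep(Inf, p), stats::qlogis(0.99), log(20))
  start[p + 1L] <- min(max(start[p + 1L], lower[p + 1L]), upper[p + 1L])
  fit <- tryCatch(
    stats::nlminb(start, neg, lower = lower, upper = upper,
                  control = list(iter.max = 300, eval.max = 600)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    fit$value <- fit$objective
    fit$hessian <- tryCatch(stats::optimHess(fit$par, neg),
                            error = function(e)
                              matrix(NA_real_, p + 2L, p + 2L))
  }
  if (is.null(fit)) {
    return(new_bbfit(stats::setNames(rep(NA_real_, p), nm),
                     stats::setNames(rep(NA_real_, p), nm), NA_real_,
                     matrix(NA_real_, p, p), NA_real_, FALSE, FALSE,
                     "mixed_bb", k, n, X, cl, sigma_b = NA_real_,
                     df = p + 2))
  }
  beta <- stats::setNames(fit$par[seq_len(p)], nm)
  rho <- stats::plogis(fit$par[p + 1L])
  sigma_b <- unname(exp(fit$par[p + 2L]))
  vc <- tryCatch(solve(fit$hessian), error = function(e)
    matrix(NA_real_, p + 2L, p + 2L))
  se <- sqrt(pmax(diag(vc)[seq_len(p)], 0))
  if (!all(is.finite(se)) || !all(se > 0)) {
    # boundary rho or sigma_b: profile out the variance parameters
    vc_b <- tryCatch(solve(fit$hessian[seq_len(p), seq_len(p),
                                       drop = FALSE]),
                     error = function(e) NULL)
    if (!is.null(vc_b) && all(is.finite(vc_b))) {
      vc <- matrix(NA_real_, p + 2L, p + 2L)
      vc[seq_len(p), seq_len(p)] <- vc_b
      se <- sqrt(pmax(diag(vc_b), 0))
    }
  }
  converged <- port_converged(fit) && all(is.finite(se)) && all(se > 0)
  new_bbfit(beta, stats::setNames(se, nm), rho,
            vc[seq_len(p), seq_len(p), drop = FALSE], -fit$value,
            converged, FALSE, "mixed_bb", k, n, X, cl,
            sigma_b = sigma_b, df = p + 2)
}

#' @export
print.bbfit <- function(x, ...) {
  cat(sprintf("%s fit (%d observations)\n",
              switch(x$method, betabinom = "Beta-binomial regression",
                     quasibinom = "Quasi-binomial regression",
                     mixed_bb = "Beta-binomial mixed model", x$method),
              x$nobs))
  cat("Coefficients (logit scale):\n")
  print(round(x$coefficients, 4))
  if (!is.na(x$rho)) cat(sprintf("rho (intra-class correlation): %.4f\n", x$rho))
  if (!is.na(x$dispersion)) cat(sprintf("dispersion: %.3f\n", x$dispersion))
  if (!is.na(x$sigma_b)) cat(sprintf("sigma_b (random intercept sd): %.4f\n",
                                     x$sigma_b))
  if (x$boundary) cat("NOTE: boundary fit (all counts on one allele)\n")
  if (!x$converged) cat("WARNING: fit did not converge\n")
  invisible(x)
}

#' @export
summary.bbfit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = object$z, `Pr(>|z|)` = object$p.values)
  structure(list(coefficients = tab, rho = object$rho,
                 sigma_b = object$sigma_b, dispersion = object$dispersion,
                 logLik = object$logLik, converged = object$converged,
                 boundary = object$boundary, method = object$method,
                 nobs = object$nobs, call = object$call),
            class = "summary.bbfit")
}

#' @export
print.summary.bbfit <- function(x, ...) {
  cat(sprintf("Call: %s\n\n", deparse(x$call)))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  if (!is.na(x$rho)) cat(sprintf("\nrho: %.4f", x$rho))
  if (!is.na(x$sigma_b)) cat(sprintf("  sigma_b: %.4f", x$sigma_b))
  if (!is.na(x$logLik)) cat(sprintf("  logLik: %.2f", x$logLik))
  cat(sprintf("  n: %d\n", x$nobs))
  invisible(x)
}

#' @export
coef.bbfit <- function(object, ...) object$coefficients

#' @export
vcov.bbfit <- function(object, ...) object$vcov

#' @export
logLik.bbfit <- function(object, ...) {
  structure(object$logLik, df = object$df, nobs = object$nobs,
            class = "logLik")
}

#' @export
nobs.bbfit <- function(object, ...) object$nobs

#' @export
predict.bbfit <- function(object, newdata = NULL,
                          type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$X else
    stats::model.matrix(stats::delete.response(stats::terms(
      stats::formula(object$call$formula))), newdata)
  eta <- drop(X %*% object$coefficients)
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
residuals.bbfit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  mu <- stats::plogis(drop(object$X %*% object$coefficients))
  resp <- object$k / object$n - mu
  if (type == "response") return(resp)
  rho <- if (is.na(object$rho)) 0 else object$rho
  v <- mu * (1 - mu) * (1 + (object$n - 1) * rho) / object$n
  resp / sqrt(v)
}

#' @export
simulate.bbfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- stats::plogis(drop(object$X %*% object$coefficients))
  rho <- if (is.na(object$rho)) 0 else object$rho
  out <- as.data.frame(replicate(nsim, rbetabinom(object$nobs, object$n,
                                                  mu, rho)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
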