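# Covariance estimation: finite-difference Hessian and per-row scores in the
# unconstrained parameterisation, mapped to the reported parameterisation by
# the delta method (numerical Jacobian of the transform).

cov_draws <- function(fit) {
  if (fit$variant != "DZIOPC") return(NULL)
  nd <- fit$control$se_draws
  if (is.null(nd)) nd <- fit$control$n_draws
  ghk_draws(fit$obs$n, nd, fit$control$seed, fit$control$antithetic)
}

rowwise_loglik_fn <- function(fit, draws = cov_draws(fit)) {
  obs <- fit$obs
  function(u) {
    params <- unpack_params(u, fit$skel)
    p <- observed_probs(params, obs, draws = draws)
    log(pmax(p, PROB_FLOOR))
  }
}

# n x p matrix of per-row score vectors by central differences
score_matrix <- function(fit, step = NULL) {
  if (is.null(step)) step <- fit$control$fd_step
  u <- fit$u
  if (fit$variant == "DZIOPC")
    return(dziopc_score_matrix(u, fit$skel, fit$obs, cov_draws(fit), step))
  f <- rowwise_loglik_fn(fit)
  p <- length(u)
  S <- matrix(0, fit$n_obs, p)
  for (k in seq_len(p)) {
    h <- step * (1 + abs(u[k]))
    up <- u; up[k] <- u[k] + h
    um <- u; um[k] <- u[k] - h
    S[, k] <- (f(up) - f(um)) / (2 * h)
  }
  S
}

# finite-difference Hessian of the total log-likelihood
total_loglik_fn <- function(fit) {
  f <- rowwise_loglik_fn(fit)
  function(u) sum(f(u))
}

loglik_hessian <- function(fit) {
  if (fit$variant == "DZIOPC")
    dziopc_batch_hessian(fit$u, fit$skel, fit$obs, cov_draws(fit),
                         fit$control$fd_step)
  else fd_hessian(total_loglik_fn(fit), fit$u, fit$control$fd_step)
}

fd_hessian <- function(fn, u, step) {
  p <- length(u)
  H <- matrix(0, p, p)
  h <- step * (1 + abs(u))
  f0 <- fn(u)
  shift <- function(k, s) { v <- u; v[k] <- v[k] + s * h[k]; v }
  for (k in seq_len(p))
    H[k, k] <- (fn(shift(k, 1)) - 2 * f0 + fn(shift(k, -1))) / h[k]^2
  if (p > 1L) {
    for (k in seq_len(p - 1L)) for (l in (k + 1L):p) {
      v1 <- u; v1[c(k, l)] <- v1[c(k, l)] + c(h[k], h[l])
      v2 <- u; v2[c(k, l)] <- v2[c(k, l)] + c(h[k], -h[l])
      v3 <- u; v3[c(k, l)] <- v3[c(k, l)] + c(-h[k], h[l])
      v4 <- u; v4[c(k, l)] <- v4[c(k, l)] - c(h[k], h[l])
      H[k, l] <- H[l, k] <- (fn(v1) - fn(v2) - fn(v3) + fn(v4)) /
        (4 * h[k] * h[l])
    }
  }
  (H + t(H)) / 2
}

# Jacobian of the reported parameter vector w.r.t. the unconstrained one
transform_jacobian <- function(fit, step = 1e-6) {
  u <- fit$u
  skel <- fit$skel
  th <- function(v) params_to_theta(unpack_params(v, skel), skel)
  p <- length(u)
  t0 <- th(u)
  Jm <- matrix(0, length(t0), p)
  for (k in seq_len(p)) {
    h <- step * (1 + abs(u[k]))
    up <- u; up[k] <- u[k] + h
    um <- u; um[k] <- u[k] - h
    Jm[, k] <- (th(up) - th(um)) / (2 * h)
  }
  Jm
}

solve_neg_hessian <- function(H, names) {
  ev <- eigen(-H, symmetric = TRUE)
  if (min(ev$values) <= 0) {
    worst <- names[which.max(abs(ev$vectors[, which.min(ev$values)]))]
    stop("Hessian is singular or not negative definite; ",
         "weakly identified direction loads mostly on '", worst, "'")
  }
  ev$vectors %*% diag(1 / ev$values, length(ev$values)) %*% t(ev$vectors)
}

fit_covariances <- function(fit, type = c("sandwich", "hessian", "opg")) {
  type <- match.arg(type)
  S <- score_matrix(fit)
  B <- crossprod(S)
  Jm <- transform_jacobian(fit)
  nm <- fit$skel$names
  out <- list(robust = NULL, hessian = NULL, note = NULL)
  if (type == "opg") {
    Binv <- tryCatch(solve(B), error = function(e)
      stop("outer-product-of-scores matrix is singular"))
    out$robust <- Jm %*% Binv %*% t(Jm)
    out$note <- "opg"
  } else {
    H <- loglik_hessian(fit)
    Hinv <- solve_neg_hessian(H, nm)
    out$hessian <- Jm %*% Hinv %*% t(Jm)
    if (type == "sandwich")
      out$robust <- Jm %*% (Hinv %*% B %*% Hinv) %*% t(Jm)
    else out$robust <- out$hessian
  }
  for (w in c("robust", "hessian")) {
    if (!is.null(out[[w]])) {
      out[[w]] <- (out[[w]] + t(out[[w]])) / 2
      dimnames(out[[w]]) <- list(nm, nm)
    }
  }
  out
}

#' Robust (sandwich) covariance of a fitted model
#'
#' Recomputes the heteroscedasticity-robust covariance
#' \eqn{H^{-1} (\sum_i g_i g_i') H^{-1}} at the estimates, with per-row
#' scores and the Hessian obtained by central finite differences in the
#' unconstrained parameterisation and mapped to the reported
#' parameterisation through the transform Jacobian.
#'
#' @param fit a fitted `"dziop"` object.
#' @return symmetric covariance matrix for [coef()] of the fit.
#' @export
sandwich_cov <- function(fit) {
  stopifnot(inherits(fit, "dziop"))
  fit_covariances(fit, "sandwich")$robust
}

#' Likelihood-ratio test of error independence
#'
#' Tests \eqn{\Omega_3 = I_3} (no cross-equation error correlation) by
#' comparing the correlated fit against its uncorrelated nested counterpart:
#' the statistic is \eqn{2(\ell_C - \ell)}, clipped at zero because a
#' simulated likelihood can fall microscopically below the analytic one, and
#' referred to a chi-square with as many degrees of freedom as freed
#' correlations (3 for DZIOPC vs DZIOP).
#'
#' @param fit_corr correlated fit (DZIOPC or ZIOPC).
#' @param fit_uncorr nested uncorrelated fit (DZIOP or ZIOP) on the same
#'   observations.
#' @return list with `statistic`, `df`, `p_value`, class `"dziop_lrtest"`.
#' @export
lr_independence_test <- function(fit_corr, fit_uncorr) {
  stopifnot(inherits(fit_corr, "dziop"), inherits(fit_uncorr, "dziop"))
  pair_ok <- (fit_corr$variant == "DZIOPC" && fit_uncorr$variant == "DZIOP") ||
    (fit_corr$variant == "ZIOPC" && fit_uncorr$variant == "ZIOP")
  if (!pair_ok)
    stop("expected a correlated fit and its uncorrelated counterpart (",
         "DZIOPC vs DZIOP or ZIOPC vs ZIOP)")
  if (fit_corr$n_obs != fit_uncorr$n_obs)
    stop("fits are not on the same observations")
  same_beta <- length(fit_corr$params$beta_y) == length(fit_uncorr$params$beta_y) &&
    length(fit_corr$params$beta_r) == length(fit_uncorr$params$beta_r) &&
    length(fit_corr$params$beta_m) == length(fit_uncorr$params$beta_m)
  if (!same_beta)
    stop("fits use different covariate specifications")
  df <- fit_corr$skel$nrho
  stat <- max(0, 2 * (fit_corr$loglik - fit_uncorr$loglik))
  out <- list(statistic = stat, df = df,
              p_value = stats::pchisq(stat, df, lower.tail = FALSE),
              loglik_corr = fit_corr$loglik,
              loglik_uncorr = fit_uncorr$loglik)
  class(out) <- "dziop_lrtest"
  out
}

#' @export
print.dziop_lrtest <- function(x, ...) {
  cat("Likelihood-ratio test of error independence (Omega3 = I)\n")
  cat(sprintf("  LR = %.4f, df = %d, p = %.4g\n", x$statistic, x$df,
              x$p_value))
  invisible(x)
}
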