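#' @export
print.dziop <- function(x, ...) {
  cat(sprintf("%s model, n = %d, categories 0..%d\n", x$variant, x$n_obs,
              x$J))
  cat(sprintf("log-likelihood %.3f  (%sconverged, %d gradient evaluations)\n",
              x$loglik, if (x$converged) "" else "NOT ", x$n_iterations))
  cat("coefficients:\n")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.dziop <- function(object, ...) object$coefficients

#' @export
vcov.dziop <- function(object, type = c("robust", "hessian"), ...) {
  type <- match.arg(type)
  V <- if (type == "robust") object$cov_robust else object$cov_hessian
  if (is.null(V))
    stop("covariance (", type, ") not available",
         if (!is.null(object$cov_note)) paste0(": ", object$cov_note))
  V
}

#' @export
logLik.dziop <- function(object, ...) {
  structure(object$loglik, df = object$skel$npar, nobs = object$n_obs,
            class = "logLik")
}

#' @export
summary.dziop <- function(object, ...) {
  se <- if (!is.null(object$cov_robust)) sqrt(pmax(diag(object$cov_robust), 0))
  else rep(NA_real_, length(object$coefficients))
  z <- object$coefficients / se
  p <- 2 * pnorm(-abs(z))
  tab <- cbind(Estimate = object$coefficients, `Robust SE` = se,
               `z value` = z, `Pr(>|z|)` = p)
  out <- list(fit = object, table = tab)
  class(out) <- "summary.dziop"
  out
}

#' @export
print.summary.dziop <- function(x, digits = 4, ...) {
  f <- x$fit
  cat(sprintf("%s model fit by maximum %slikelihood\n", f$variant,
              if (f$variant == "DZIOPC") "simulated " else ""))
  cat(sprintf("n = %d, J = %d, log-likelihood = %.3f, AIC = %.1f\n",
              f$n_obs, f$J, f$loglik, 2 * f$skel$npar - 2 * f$loglik))
  if (f$variant == "DZIOPC")
    cat(sprintf("GHK: %d antithetic Halton draws per observation, seed %d\n",
                f$control$n_draws, f$control$seed))
  cat(sprintf("converged: %s (|grad| = %.2e)\n", f$converged,
              f$gradient_norm))
  if (!is.null(f$cov_note)) cat("covariance note:", f$cov_note, "\n")
  cat("\n")
  tt <- x$table
  star <- stars_at(tt[, 4])
  out <- cbind(format(round(tt, digits)), ` ` = star)
  eq <- sub(":.*", "", rownames(tt))
  blocks <- list(`Participation (r)` = "r", `Truthful reporting (m)` = "m",
                 `Consumption (y)` = "y")
  for (b in names(blocks)) {
    sel <- eq == blocks[[b]]
    if (any(sel)) {
      cat(b, "\n")
      print(out[sel, , drop = FALSE], quote = FALSE)
    }
  }
  rest <- !eq %in% c("r", "m", "y")
  if (any(rest)) {
    cat("Thresholds / correlations\n")
    print(out[rest, , drop = FALSE], quote = FALSE)
  }
  cat("---\nSignif.: ** 5%, * 10%\n")
  invisible(x)
}

#' Predicted probabilities and classifications
#'
#' @param object a fitted `"dziop"` model.
#' @param newdata optional covariate table (defaults to the fitting data).
#' @param type `"prob"` for the n x (J+1) matrix of category probabilities,
#'   `"class"` for the modal category, `"zero"` for the three zero
#'   components per row.
#' @param ... unused.
#' @export
predict.dziop <- function(object, newdata = NULL,
                          type = c("prob", "class", "zero"), ...) {
  type <- match.arg(type)
  obs <- if (is.null(newdata)) object$obs
  else design_only(as.data.frame(newdata), object$obs$spec, object$J)
  cp <- compute_probs(object$params, obs,
                      n_draws = object$control$n_draws,
                      seed = object$control$seed,
                      antithetic = object$control$antithetic)
  switch(type,
         prob = cp$probs,
         class = max.col(cp$probs) - 1L,
         zero = cp$comps)
}

#' Simulate outcomes from a fitted model
#'
#' Draws new ordinal outcomes (given the covariates used in fitting, or new
#' ones) from the fitted three-equation process.
#'
#' @param object a fitted `"dziop"` model.
#' @param nsim number of simulated outcome vectors.
#' @param seed integer seed.
#' @param newdata optional covariate table.
#' @param ... unused.
#' @return a data frame with `nsim` columns of simulated outcomes.
#' @export
simulate.dziop <- function(object, nsim = 1, seed = 1L, newdata = NULL, ...) {
  obs <- if (is.null(newdata)) object$obs
  else design_only(as.data.frame(newdata), object$obs$spec, object$J)
  pa <- object$params
  has_r <- variant_has_r(object$variant)
  has_m <- variant_has_m(object$variant)
  set.seed(seed)
  L <- t(chol(corr3(pa$rho)))
  thr <- threshold_matrix(pa, obs)
  out <- vector("list", nsim)
  ar <- if (has_r) drop(obs$Xr %*% pa$beta_r)
  am <- if (has_m) drop(obs$Xm %*% pa$beta_m)
  ay <- drop(obs$Xy %*% pa$beta_y)
  for (s in seq_len(nsim)) {
    eps <- matrix(stats::rnorm(3 * obs$n), obs$n, 3) %*% t(L)
    r <- if (has_r) as.integer(ar + eps[, 1] > 0) else 1L
    m <- if (has_m) as.integer(am + eps[, 2] > 0) else 1L
    ys <- ay + eps[, 3]
    # yt = #{thresholds below ys}, with the lowest boundary at 0
    yt <- as.integer(ys > 0)
    for (j in seq_len(obs$J - 1L)) yt <- yt + as.integer(ys > thr[, j])
    out[[s]] <- r * m * yt
  }
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Observed versus predicted category frequencies
#'
#' @param x a fitted `"dziop"` model.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.dziop <- function(x, ...) {
  obsf <- tabulate(x$obs$y + 1L, nbins = x$J + 1L) / x$n_obs
  prdf <- colMeans(predict(x, type = "prob"))
  m <- rbind(observed = obsf, predicted = prdf)
  colnames(m) <- 0:x$J
  graphics::barplot(m, beside = TRUE, legend.text = TRUE,
                    xlab = "outcome category", ylab = "frequency", ...)
  invisible(m)
}
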