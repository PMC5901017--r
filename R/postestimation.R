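# Partial effects decomposed over the three zero sources, and prior /
# posterior attribution of observed zeros (the model's headline outputs).

# observation container without an outcome, for probability summaries on
# perturbed covariate tables
design_only <- function(data, spec, J) {
  n <- nrow(data)
  obs <- list(
    y = integer(n), n = n, J = J,
    Xr = build_one_design(data, spec$xr, spec$intercept_r, "participation", n),
    Xm = build_one_design(data, spec$xm, spec$intercept_m, "misreporting", n),
    Xy = build_one_design(data, spec$xy, spec$intercept_y, "consumption", n),
    Zt = build_one_design(data, spec$thresholds, FALSE, "threshold", n),
    spec = spec)
  class(obs) <- "dziop_obs"
  obs
}

# averaged probability summary: c(comp1..3, zero_total, p0..pJ)
prob_summary <- function(params, data, spec, J, ghk) {
  obs <- design_only(data, spec, J)
  cp <- compute_probs(params, obs, n_draws = ghk$n_draws, seed = ghk$seed,
                      antithetic = ghk$antithetic)
  comps <- colMeans(cp$comps)
  probs <- colMeans(cp$probs)
  c(comps, zero_total = sum(comps), probs)
}

summary_targets <- function(J)
  c("nonparticipation", "misreporting", "zero_consumption", "zero_total",
    paste0("cat_", 0:J))

used_columns <- function(spec)
  unique(c(spec$xr, spec$xm, spec$xy, spec$thresholds))

is_binary_col <- function(x) all(x %in% c(0, 1))

#' Partial effects on the zero components and category probabilities
#'
#' For each covariate, the effect on the probability of each zero source
#' (nonparticipation; participation and misreporting; participation,
#' truthful reporting and zero consumption), on the overall zero
#' probability, and on every category probability.  A covariate appearing
#' in several equations receives its total effect through all channels.
#' The three component effects sum to the overall zero effect, and effects
#' across all categories sum to zero.
#'
#' Continuous covariates get central numerical derivatives; binary
#' covariates a discrete 0-to-1 change by default.  Standard errors use the
#' delta method with a numerical Jacobian over the reported parameters and
#' the fit's robust covariance.
#'
#' @param fit a fitted `"dziop"` object (needs the original data; fits from
#'   [dziop()] carry it, otherwise pass `data`).
#' @param data covariate table; defaults to the data stored in the fit.
#' @param mode `"at_means"` (evaluate at the arithmetic means of every
#'   design column, including dummies and each quadratic term's own mean) or
#'   `"average"` (average of row-level effects).
#' @param dummies `"discrete"` (0-to-1 change, default) or `"derivative"`.
#' @param covariates which columns to report; default: all columns used by
#'   any equation.  Columns absent from every equation get effect 0, SE 0.
#' @param se compute delta-method standard errors (default \code{TRUE}).
#' @param step numerical derivative step for continuous covariates.
#' @return object of class `"dziop_margins"`: long table with columns
#'   `term`, `target`, `estimate`, `se`.
#' @export
partial_effects <- function(fit, data = fit$data,
                            mode = c("at_means", "average"),
                            dummies = c("discrete", "derivative"),
                            covariates = NULL, se = TRUE, step = 1e-6) {
  stopifnot(inherits(fit, "dziop"))
  mode <- match.arg(mode)
  dummies <- match.arg(dummies)
  if (is.null(data))
    stop("no data stored in the fit; supply `data`")
  data <- as.data.frame(data)
  spec <- fit$obs$spec
  J <- fit$J
  ghk <- list(n_draws = fit$control$n_draws, seed = fit$control$seed,
              antithetic = fit$control$antithetic)
  used <- used_columns(spec)
  if (is.null(covariates)) covariates <- used
  base <- if (mode == "at_means")
    as.data.frame(lapply(data[, names(data) != spec$outcome, drop = FALSE],
                         function(x) mean(as.numeric(x))))
  else data
  eval_effect <- function(theta, v) {
    params <- theta_to_params(theta, fit$skel)
    x <- as.numeric(data[[v]])
    if (dummies == "discrete" && is_binary_col(x)) {
      d1 <- base; d1[[v]] <- 1
      d0 <- base; d0[[v]] <- 0
      prob_summary(params, d1, spec, J, ghk) -
        prob_summary(params, d0, spec, J, ghk)
    } else {
      dp <- base; dp[[v]] <- dp[[v]] + step
      dm <- base; dm[[v]] <- dm[[v]] - step
      (prob_summary(params, dp, spec, J, ghk) -
         prob_summary(params, dm, spec, J, ghk)) / (2 * step)
    }
  }
  theta0 <- fit$coefficients
  tg <- summary_targets(J)
  rows <- list()
  for (v in covariates) {
    if (!v %in% names(data))
      stop("covariate not found in data: ", v)
    if (!v %in% used) {
      rows[[v]] <- data.frame(term = v, target = tg, estimate = 0, se = 0)
      next
    }
    est <- eval_effect(theta0, v)
    ses <- rep(NA_real_, length(est))
    if (se) {
      if (is.null(fit$cov_robust))
        stop("fit has no covariance; refit with se != 'none' or use se = FALSE")
      p <- length(theta0)
      G <- matrix(0, length(est), p)
      for (k in seq_len(p)) {
        h <- 1e-5 * (1 + abs(theta0[k]))
        tp <- theta0; tp[k] <- tp[k] + h
        tm <- theta0; tm[k] <- tm[k] - h
        G[, k] <- (eval_effect(tp, v) - eval_effect(tm, v)) / (2 * h)
      }
      V <- G %*% fit$cov_robust %*% t(G)
      ses <- sqrt(pmax(diag(V), 0))
    }
    rows[[v]] <- data.frame(term = v, target = tg, estimate = unname(est),
                            se = ses)
  }
  out <- list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
              mode = mode, dummies = dummies, variant = fit$variant, J = J)
  class(out) <- "dziop_margins"
  out
}

stars_at <- function(p) ifelse(p < 0.05, "**", ifelse(p < 0.10, "*", ""))

#' @export
print.dziop_margins <- function(x, digits = 3, ...) {
  cat(sprintf("Partial effects (%s, dummies: %s), variant %s\n",
              gsub("_", " ", x$mode), x$dummies, x$variant))
  cat("Decomposition of the effect on Pr(y = 0):\n")
  keep <- c("nonparticipation", "misreporting", "zero_consumption",
            "zero_total")
  wide <- NULL
  for (term in unique(x$table$term)) {
    tt <- x$table[x$table$term == term & x$table$target %in% keep, ]
    est <- tt$estimate[match(keep, tt$target)]
    sev <- tt$se[match(keep, tt$target)]
    cell <- ifelse(is.na(sev), sprintf("%.*f", digits, est),
                   sprintf("%.*f (%.*f)%s", digits, est, digits, sev,
                           stars_at(2 * pnorm(-abs(est / ifelse(sev > 0, sev, Inf))))))
    wide <- rbind(wide, cell)
  }
  dimnames(wide) <- list(unique(x$table$term),
                         c("nonpart", "misreport", "zero_cons", "overall"))
  print(wide, quote = FALSE)
  invisible(x)
}

#' Turn a margins object into a wide data frame
#' @param x a `"dziop_margins"` object.
#' @param ... unused.
#' @export
as.data.frame.dziop_margins <- function(x, ...) {
  est <- stats::reshape(x$table[, c("term", "target", "estimate")],
                 idvar = "term", timevar = "target", direction = "wide")
  names(est) <- sub("^estimate\\.", "", names(est))
  est
}

# shared internals for prior/posterior zero summaries -----------------------

components_fn <- function(fit, obs) {
  ghk <- list(n_draws = fit$control$n_draws, seed = fit$control$seed,
              antithetic = fit$control$antithetic)
  function(theta) {
    params <- theta_to_params(theta, fit$skel)
    compute_probs(params, obs, n_draws = ghk$n_draws, seed = ghk$seed,
                  antithetic = ghk$antithetic)$comps
  }
}

# Standard error of a sample-average functional of the fitted parameters:
# delta-method parameter term, the sampling variability of the average, and
# (when the average runs over the estimation sample itself) the
# cross-covariance between the two, obtained from per-row scores and the
# Hessian -- the estimate and the average share the same data, so the cross
# term is first-order, not ignorable.
avg_delta_se <- function(fit, fn_avg, per_row, rows = NULL) {
  theta0 <- fit$coefficients
  p <- length(theta0)
  a0 <- fn_avg(theta0)
  G <- matrix(0, length(a0), p)
  for (k in seq_len(p)) {
    h <- 1e-5 * (1 + abs(theta0[k]))
    tp <- theta0; tp[k] <- tp[k] + h
    tm <- theta0; tm[k] <- tm[k] - h
    G[, k] <- (fn_avg(tp) - fn_avg(tm)) / (2 * h)
  }
  V <- G %*% fit$cov_robust %*% t(G)
  nr <- nrow(per_row)
  Cc <- sweep(per_row, 2, colMeans(per_row))
  V <- V + crossprod(Cc) / nr^2
  if (!is.null(rows)) {
    cross <- tryCatch({
      S <- score_matrix(fit)[rows, , drop = FALSE]
      H <- loglik_hessian(fit)
      Jm <- transform_jacobian(fit)
      cu <- solve(-H, crossprod(S, Cc) / nr)
      G %*% (Jm %*% cu)
    }, error = function(e) NULL)
    if (!is.null(cross)) V <- V + cross + t(cross)
  }
  sqrt(pmax(diag(V), 0))
}

#' Posterior attribution of observed zeros
#'
#' For every row with an observed zero, the conditional probabilities that
#' the zero originated from nonparticipation, misreporting, or truthful zero
#' consumption: the prior zero components normalised by their sum.  Sample
#' averages over the zero rows are reported with delta-method standard
#' errors (parameter uncertainty plus the sampling variability of the
#' average).
#'
#' @param fit a fitted DZIOP or DZIOPC model.
#' @param obs observations; defaults to those stored in the fit.
#' @param se compute standard errors for the averages.
#' @return object of class `"dziop_posterior"`: per-row `shares` (rows with
#'   y = 0 only), `average`, `se`, `n_zero`.
#' @export
posterior_zero_shares <- function(fit, obs = fit$obs, se = TRUE) {
  stopifnot(inherits(fit, "dziop"))
  if (!variant_has_m(fit$variant))
    stop("posterior zero attribution needs a DZIOP or DZIOPC fit")
  z <- obs$y == 0
  if (!any(z)) stop("no observed zeros in the data")
  obs0 <- subset_obs(obs, z)
  fn <- components_fn(fit, obs0)
  comps <- fn(fit$coefficients)
  shares <- comps / rowSums(comps)
  avg <- colMeans(shares)
  ses <- rep(NA_real_, 3)
  if (se) {
    if (is.null(fit$cov_robust))
      stop("fit has no covariance; refit with se != 'none' or use se = FALSE")
    fn_avg <- function(theta) {
      cc <- fn(theta)
      colMeans(cc / rowSums(cc))
    }
    same_sample <- identical(obs$y, fit$obs$y) && obs$n == fit$obs$n
    ses <- avg_delta_se(fit, fn_avg, shares,
                        rows = if (same_sample) which(z))
  }
  structure(list(shares = shares, average = avg, se = ses,
                 n_zero = sum(z), variant = fit$variant),
            class = "dziop_posterior")
}

#' @export
print.dziop_posterior <- function(x, digits = 3, ...) {
  cat(sprintf("Posterior origin of %d observed zeros (%s)\n", x$n_zero,
              x$variant))
  m <- rbind(share = x$average, se = x$se)
  print(round(m, digits))
  invisible(x)
}

#' Prior (marginal) zero decomposition, averaged over the sample
#'
#' Averages the three zero components over all rows; their sum is the
#' average model probability of an observed zero.  With standard errors this
#' is the machinery behind a predicted-zero summary table: one row of
#' marginal probabilities and, together with [posterior_zero_shares()], one
#' row of posterior shares.
#'
#' @inheritParams posterior_zero_shares
#' @return object of class `"dziop_priorzero"`: `average` (3 components),
#'   `total`, `se` (length 4: components then total).
#' @export
prior_zero_summary <- function(fit, obs = fit$obs, se = TRUE) {
  stopifnot(inherits(fit, "dziop"))
  if (!variant_has_m(fit$variant))
    stop("the zero decomposition needs a DZIOP or DZIOPC fit")
  fn <- components_fn(fit, obs)
  comps <- fn(fit$coefficients)
  avg <- colMeans(comps)
  ses <- rep(NA_real_, 4)
  if (se) {
    if (is.null(fit$cov_robust))
      stop("fit has no covariance; refit with se != 'none' or use se = FALSE")
    fn_avg <- function(theta) {
      cc <- fn(theta)
      c(colMeans(cc), sum(colMeans(cc)))
    }
    same_sample <- identical(obs$y, fit$obs$y) && obs$n == fit$obs$n
    ses <- avg_delta_se(fit, fn_avg, cbind(comps, rowSums(comps)),
                        rows = if (same_sample) seq_len(obs$n))
  }
  structure(list(average = avg, total = sum(avg), se = ses,
                 variant = fit$variant, n = obs$n),
            class = "dziop_priorzero")
}

#' @export
print.dziop_priorzero <- function(x, digits = 3, ...) {
  cat(sprintf("Average zero decomposition over %d rows (%s)\n", x$n,
              x$variant))
  m <- rbind(probability = c(x$average, full = x$total), se = x$se)
  colnames(m) <- c(names(x$average), "full")
  print(round(m, digits))
  invisible(x)
}

#' Two-row predicted-zero table (marginal and posterior)
#'
#' Convenience wrapper combining [prior_zero_summary()] and
#' [posterior_zero_shares()] into the 2 x 4 layout commonly reported:
#' marginal probabilities of the three zero types plus their total, and
#' posterior shares plus their total of one.
#'
#' @inheritParams posterior_zero_shares
#' @return a data frame with rows `marginal` and `posterior`.
#' @export
zero_summary_table <- function(fit, obs = fit$obs, se = TRUE) {
  pr <- prior_zero_summary(fit, obs, se = se)
  po <- posterior_zero_shares(fit, obs, se = se)
  out <- data.frame(
    nonparticipation = c(pr$average[1], po$average[1]),
    misreporting = c(pr$average[2], po$average[2]),
    zero_consumption = c(pr$average[3], po$average[3]),
    full = c(pr$total, 1),
    row.names = c("marginal", "posterior"))
  attr(out, "se") <- rbind(marginal = pr$se,
                           posterior = c(po$se, NA))
  out
}

# row subset of an observation set
subset_obs <- function(obs, idx) {
  out <- list(y = obs$y[idx], n = sum(idx | FALSE) , J = obs$J,
              Xr = obs$Xr[idx, , drop = FALSE],
              Xm = obs$Xm[idx, , drop = FALSE],
              Xy = obs$Xy[idx, , drop = FALSE],
              Zt = obs$Zt[idx, , drop = FALSE],
              spec = obs$spec)
  out$n <- length(out$y)
  class(out) <- "dziop_obs"
  out
}
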