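#' Log-likelihood of an observation set under a parameter set
#'
#' Sum over rows of the log of the observed category's probability.
#' Probabilities are floored at 1e-300 before logging so the value is always
#' finite.
#'
#' @inheritParams category_probs
#' @return scalar log-likelihood.
#' @export
loglik <- function(params, obs, n_draws = 500L, seed = 1L,
                   antithetic = TRUE, draws = NULL) {
  stopifnot(inherits(params, "dziop_params"), inherits(obs, "dziop_obs"))
  p <- observed_probs(params, obs, draws = draws, n_draws = n_draws,
                      seed = seed, antithetic = antithetic)
  sum(log(pmax(p, PROB_FLOOR)))
}

#' Estimation settings
#'
#' @param tol_loglik relative log-likelihood improvement below which the
#'   optimiser stops (BFGS `reltol`).
#' @param tol_grad infinity-norm tolerance on the gradient of the *mean*
#'   log-likelihood required to declare convergence.
#' @param max_iter BFGS iteration cap.
#' @param n_draws,antithetic GHK settings for the simulated likelihood
#'   (DZIOPC); antithetic pairs count towards `n_draws`.
#' @param seed governs the Halton scramble; the same options and seed give a
#'   bit-identical fit.
#' @param fd_step relative step for central finite-difference gradients.
#' @param se covariance estimator: `"sandwich"` (robust, default; also
#'   stores the inverse-Hessian covariance), `"hessian"`, `"opg"`
#'   (outer product of scores; cheapest, avoids the finite-difference
#'   Hessian for expensive simulated likelihoods) or `"none"`.
#' @param se_draws GHK draws for the covariance computation (DZIOPC);
#'   defaults to `n_draws`.  Standard errors need far less draw precision
#'   than the point estimates, so a smaller value makes the sandwich
#'   affordable at large n.
#' @param optimizer `"BFGS"` (default) or `"nlminb"`, a scaled variant that
#'   preconditions the search with diagonal curvature and handles the flat
#'   misreporting/correlation directions in many fewer iterations.
#' @export
dziop_control <- function(tol_loglik = 1e-9, tol_grad = 1e-4,
                          max_iter = 600L, n_draws = 500L, seed = 1L,
                          antithetic = TRUE, fd_step = 1e-5,
                          se = c("sandwich", "hessian", "opg", "none"),
                          se_draws = NULL,
                          optimizer = c("BFGS", "nlminb")) {
  list(tol_loglik = tol_loglik, tol_grad = tol_grad,
       max_iter = as.integer(max_iter), n_draws = as.integer(n_draws),
       seed = as.integer(seed), antithetic = isTRUE(antithetic),
       fd_step = fd_step, se = match.arg(se),
       se_draws = if (!is.null(se_draws)) as.integer(se_draws),
       optimizer = match.arg(optimizer))
}

# Batched evaluation machinery for the GHK-simulated (DZIOPC) likelihood:
# many parameter configurations run through one C++ pass sharing the same
# draws, with stage reuse where a perturbation leaves the early GHK stages
# unchanged.  A configuration's "level" says how much it shares with the
# first (base) configuration: 3 = only the consumption block or thresholds
# differ, 2 = the misreporting block differs too, 1 = full recomputation
# (participation block or correlations).

# level of a single unconstrained coordinate
dziopc_level_of <- function(skel) {
  kr <- skel$kr; km <- skel$km; ky <- skel$ky
  function(k) {
    if (k <= kr) 1L
    else if (k <= kr + km) 2L
    else if (k <= kr + km + ky + skel$J - 1L) 3L
    else 1L                                   # correlation block
  }
}

# evaluate the total (or row-wise) log-likelihood at a list of
# unconstrained parameter vectors; ulist[[1]] is the base configuration
dziopc_batch_ll <- function(ulist, levels, skel, obs, draws,
                            rowwise = FALSE) {
  C <- length(ulist)
  n <- obs$n
  AR <- matrix(0, n, C); AM <- matrix(0, n, C); AY <- matrix(0, n, C)
  MU <- matrix(0, skel$J - 1L, C); LV <- matrix(0, 9L, C)
  for (c in seq_len(C)) {
    params <- unpack_params(ulist[[c]], skel)
    AR[, c] <- drop(obs$Xr %*% params$beta_r)
    AM[, c] <- drop(obs$Xm %*% params$beta_m)
    AY[, c] <- drop(obs$Xy %*% params$beta_y)
    MU[, c] <- params$mu
    R <- signed_corr3(params$rho[["rm"]], params$rho[["ry"]],
                      params$rho[["my"]], c(-1, -1, 1))
    LV[, c] <- as.vector(t(chol(R)))
  }
  cpp_ghk_dziopc_batch(AR, AM, AY, MU, LV, as.integer(levels), draws$m,
                       draws$u1, draws$u2, draws$antithetic,
                       as.integer(obs$y), rowwise)
}

# central-difference gradient (plus diagonal curvature) of the mean
# negative log-likelihood in one batched pass
dziopc_batch_gradient <- function(u, skel, obs, draws, step) {
  p <- length(u)
  n <- obs$n
  lev <- dziopc_level_of(skel)
  h <- step * (1 + abs(u))
  ulist <- vector("list", 2L * p + 1L)
  levels <- integer(2L * p + 1L)
  ulist[[1L]] <- u
  levels[1L] <- 3L
  for (k in seq_len(p)) {
    up <- u; up[k] <- u[k] + h[k]
    um <- u; um[k] <- u[k] - h[k]
    ulist[[2L * k]] <- up
    ulist[[2L * k + 1L]] <- um
    levels[c(2L * k, 2L * k + 1L)] <- lev(k)
  }
  ll <- dziopc_batch_ll(ulist, levels, skel, obs, draws)
  g <- numeric(p)
  curv <- numeric(p)
  for (k in seq_len(p)) {
    g[k] <- -(ll[2L * k] - ll[2L * k + 1L]) / (2 * h[k]) / n
    curv[k] <- -(ll[2L * k] - 2 * ll[1L] + ll[2L * k + 1L]) / h[k]^2 / n
  }
  list(value = -ll[1L] / n, gradient = g, curvature = curv)
}

# per-row score matrix by batched central differences
dziopc_score_matrix <- function(u, skel, obs, draws, step) {
  p <- length(u)
  lev <- dziopc_level_of(skel)
  h <- step * (1 + abs(u))
  ulist <- vector("list", 2L * p + 1L)
  levels <- integer(2L * p + 1L)
  ulist[[1L]] <- u
  levels[1L] <- 3L
  for (k in seq_len(p)) {
    up <- u; up[k] <- u[k] + h[k]
    um <- u; um[k] <- u[k] - h[k]
    ulist[[2L * k]] <- up
    ulist[[2L * k + 1L]] <- um
    levels[c(2L * k, 2L * k + 1L)] <- lev(k)
  }
  LL <- dziopc_batch_ll(ulist, levels, skel, obs, draws, rowwise = TRUE)
  S <- matrix(0, obs$n, p)
  for (k in seq_len(p))
    S[, k] <- (LL[, 2L * k] - LL[, 2L * k + 1L]) / (2 * h[k])
  S
}

# finite-difference Hessian of the total log-likelihood in one batched pass
dziopc_batch_hessian <- function(u, skel, obs, draws, step) {
  p <- length(u)
  lev <- dziopc_level_of(skel)
  h <- step * (1 + abs(u))
  ulist <- list(u)
  levels <- 3L
  idx_diag <- matrix(0L, p, 2)
  for (k in seq_len(p)) {
    up <- u; up[k] <- u[k] + h[k]
    um <- u; um[k] <- u[k] - h[k]
    ulist <- c(ulist, list(up, um))
    levels <- c(levels, rep(lev(k), 2L))
    idx_diag[k, ] <- c(length(ulist) - 1L, length(ulist))
  }
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  idx_cross <- matrix(0L, nrow(pairs), 4)
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      k <- pairs[r, 1]; l <- pairs[r, 2]
      lv <- min(lev(k), lev(l))
      for (s in 1:4) {
        sk <- c(1, 1, -1, -1)[s]; sl <- c(1, -1, 1, -1)[s]
        v <- u; v[k] <- v[k] + sk * h[k]; v[l] <- v[l] + sl * h[l]
        ulist <- c(ulist, list(v))
        levels <- c(levels, lv)
        idx_cross[r, s] <- length(ulist)
      }
    }
  }
  ll <- dziopc_batch_ll(ulist, levels, skel, obs, draws)
  H <- matrix(0, p, p)
  for (k in seq_len(p))
    H[k, k] <- (ll[idx_diag[k, 1]] - 2 * ll[1] + ll[idx_diag[k, 2]]) / h[k]^2
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      k <- pairs[r, 1]; l <- pairs[r, 2]
      v <- ll[idx_cross[r, ]]
      H[k, l] <- H[l, k] <- (v[1] - v[2] - v[3] + v[4]) / (4 * h[k] * h[l])
    }
  }
  (H + t(H)) / 2
}

# diagonal curvature of the mean negative log-likelihood, used to scale the
# nlminb search (preconditions the flat, weakly identified directions)
diag_curvature <- function(negll, u, f0, step = 1e-3) {
  p <- length(u)
  curv <- numeric(p)
  for (k in seq_len(p)) {
    h <- step * (1 + abs(u[k]))
    up <- u; up[k] <- u[k] + h
    um <- u; um[k] <- u[k] - h
    curv[k] <- (negll(up) - 2 * f0 + negll(um)) / h^2
  }
  curv
}

# central finite-difference gradient with relative steps
fd_gradient <- function(fn, u, step) {
  p <- length(u)
  g <- numeric(p)
  for (k in seq_len(p)) {
    h <- step * (1 + abs(u[k]))
    up <- u; up[k] <- u[k] + h
    um <- u; um[k] <- u[k] - h
    g[k] <- (fn(up) - fn(um)) / (2 * h)
  }
  g
}

#' Staged starting values
#'
#' Warm start built in stages: a probit of `1(y > 0)` on the participation
#' design seeds `beta_r`; a plain ordered-probit fit (on all rows, mapped to
#' the `mu_0 = 0` normalisation) seeds `beta_y` and the thresholds; the
#' misreporting equation starts at zero except for an intercept of 1 (a high
#' prior probability of truthful reporting); correlations start at zero.  If
#' a stage fails it falls back to neutral values with a warning.
#'
#' @param obs a [build_design()] observation set.
#' @param variant model variant tag.
#' @return a [parameter_set()].
#' @export
starting_values <- function(obs, variant) {
  check_variant(variant)
  J <- obs$J
  cum <- cumsum(tabulate(obs$y + 1L, nbins = J + 1L) / obs$n)
  cum <- pmin(pmax(cum, 1e-4), 1 - 1e-4)
  alpha <- -qnorm(cum[1L])                       # OP intercept, mu0 = 0
  mu0 <- qnorm(cum[2:J]) + alpha
  mu0 <- pmax(mu0, cumsum(rep(1e-3, J - 1L)))    # enforce strict ordering
  naive_by <- function() {
    b <- numeric(ncol(obs$Xy))
    ic <- match("(Intercept)", colnames(obs$Xy))
    if (!is.na(ic)) b[ic] <- alpha
    b
  }
  if (variant %in% c("OP", "GOP")) {
    gam <- if (variant == "GOP")
      matrix(0, J - 1L, ncol(obs$Zt)) else NULL
    return(parameter_set(variant, beta_y = naive_by(), mu = mu0,
                         gamma = gam))
  }
  # stage (i): participation probit
  beta_r <- tryCatch({
    fitp <- stats::glm.fit(obs$Xr, as.numeric(obs$y > 0),
                           family = stats::binomial("probit"))
    b <- fitp$coefficients
    b[!is.finite(b)] <- 0
    b
  }, error = function(e) {
    warning("participation probit failed for starting values; using zeros")
    numeric(ncol(obs$Xr))
  })
  # stage (ii): plain OP warm start for the consumption block
  op <- tryCatch({
    st <- parameter_set("OP", beta_y = naive_by(), mu = mu0)
    f <- dziop_fit(obs, "OP", start = st,
                   control = dziop_control(se = "none", max_iter = 100L))
    f$params
  }, error = function(e) {
    warning("ordered-probit warm start failed; using naive values")
    parameter_set("OP", beta_y = naive_by(), mu = mu0)
  })
  beta_m <- numeric(0)
  if (variant_has_m(variant)) {
    beta_m <- numeric(ncol(obs$Xm))
    im <- match("(Intercept)", colnames(obs$Xm))
    if (!is.na(im)) beta_m[im] <- 1
  }
  parameter_set(variant, beta_r = beta_r, beta_m = beta_m,
                beta_y = op$beta_y, mu = op$mu)
}

#' Fit a model variant to an observation set
#'
#' Quasi-Newton (BFGS) maximisation of the (mean) log-likelihood in an
#' unconstrained parameterisation: log-increment thresholds and
#' tanh-transformed partial correlations, so ordering and positive
#' definiteness hold at every iterate.  For DZIOPC the likelihood is
#' simulated with the GHK simulator using draws that are fixed per
#' observation across iterations (common random numbers), which keeps the
#' objective smooth.  Gradients are central finite differences.
#'
#' Non-convergence within `max_iter` is reported through `converged = FALSE`
#' and diagnostics, not an error.
#'
#' @param obs a [build_design()] observation set.
#' @param variant model variant tag, see [dziop_variants()].
#' @param start optional [parameter_set()]; defaults to [starting_values()].
#' @param control a [dziop_control()] list.
#' @return an object of class `"dziop"`; see [dziop()] for its contents.
#' @export
dziop_fit <- function(obs, variant, start = NULL,
                      control = dziop_control()) {
  stopifnot(inherits(obs, "dziop_obs"))
  check_variant(variant)
  skel <- param_skeleton(obs, variant)
  if (is.null(start)) start <- starting_values(obs, variant)
  stopifnot(inherits(start, "dziop_params"))
  if (start$variant != variant)
    stop("starting values are for variant ", start$variant, ", not ", variant)
  draws <- if (variant == "DZIOPC")
    ghk_draws(obs$n, control$n_draws, control$seed, control$antithetic)
  else NULL
  n <- obs$n
  negll <- function(u) {
    params <- tryCatch(unpack_params(u, skel), error = function(e) NULL)
    if (is.null(params)) return(1e10)
    -loglik(params, obs, draws = draws) / n
  }
  grad <- if (variant == "DZIOPC")
    function(u) dziopc_batch_gradient(u, skel, obs, draws,
                                      control$fd_step)$gradient
  else function(u) fd_gradient(negll, u, control$fd_step)
  u0 <- pack_params(start, skel)
  f0 <- negll(u0)
  if (control$optimizer == "BFGS") {
    opt <- stats::optim(u0, negll, grad, method = "BFGS",
                        control = list(maxit = control$max_iter,
                                       reltol = control$tol_loglik))
  } else {
    curv <- if (variant == "DZIOPC")
      dziopc_batch_gradient(u0, skel, obs, draws, 1e-3)$curvature
    else diag_curvature(negll, u0, f0)
    sc <- sqrt(pmax(curv, 1e-4))
    o <- stats::nlminb(u0, negll, grad, scale = sc,
                       control = list(iter.max = control$max_iter,
                                      eval.max = 2L * control$max_iter,
                                      rel.tol = control$tol_loglik))
    opt <- list(par = o$par, value = o$objective,
                convergence = if (o$convergence == 0L) 0L else 1L,
                counts = c(`function` = unname(o$evaluations[1]),
                           gradient = unname(o$evaluations[2])),
                message = o$message)
  }
  # keep the better of start and optimum (the fit can never lose ground)
  if (opt$value > f0) {
    opt$par <- u0
    opt$value <- f0
  }
  g <- grad(opt$par)
  gnorm <- max(abs(g))
  params <- unpack_params(opt$par, skel)
  fit <- structure(list(
    params = params, skel = skel, u = opt$par,
    coefficients = params_to_theta(params, skel),
    loglik = -opt$value * n, n_obs = n, J = obs$J, variant = variant,
    gradient_norm = gnorm,
    n_iterations = unname(opt$counts["gradient"]),
    converged = (opt$convergence == 0L) && (gnorm < control$tol_grad),
    optim_message = opt$message,
    control = control, obs = obs, draws_seed = control$seed,
    cov_robust = NULL, cov_hessian = NULL, cov_note = NULL),
    class = "dziop")
  if (control$se != "none") {
    covs <- tryCatch(fit_covariances(fit, type = control$se),
                     error = function(e) {
                       list(robust = NULL, hessian = NULL,
                            note = conditionMessage(e))
                     })
    fit$cov_robust <- covs$robust
    fit$cov_hessian <- covs$hessian
    fit$cov_note <- covs$note
  }
  fit
}

#' Fit zero-inflated ordered probit models with misreported zeros
#'
#' Formula interface to [dziop_fit()].  The right-hand side has one part per
#' latent equation, separated by `|`: participation, misreporting and
#' consumption for the double-inflated variants (`y ~ xr | xm | xy`),
#' participation and consumption for ZIOP/ZIOPC, and a single part for
#' OP/GOP.  Remove an equation's intercept with `- 1` inside its part.
#'
#' @param formula multi-part model formula (see Details above).
#' @param data a data frame; the outcome column must be integer-coded 0..J.
#' @param variant model variant tag, see [dziop_variants()].
#' @param thresholds one-sided formula (or character vector) naming the
#'   threshold-equation covariates (GOP only).
#' @param start optional [parameter_set()] of starting values.
#' @param control a [dziop_control()] list.
#' @return an object of class `"dziop"` with components including
#'   `params` (estimates as a [parameter_set()]), `coefficients` (named
#'   vector), `loglik`, `cov_robust` (sandwich), `cov_hessian`,
#'   `gradient_norm`, `n_iterations`, `converged`, `n_obs`, `variant` and
#'   the estimation `control`.  Methods: `print`, `summary`, `coef`,
#'   `vcov`, `logLik`, `predict`, `simulate`, `plot`.
#' @examples
#' cfg <- cannabis_preset(design = "minimal", n = 800, seed = 42)
#' dat <- simulate_dziop(cfg)$data
#' fit <- dziop(y ~ x_r | x_m | x_c, dat, variant = "DZIOP",
#'              control = dziop_control(se = "none"))
#' fit
#' @export
dziop <- function(formula, data, variant = "DZIOP", thresholds = NULL,
                  start = NULL, control = dziop_control()) {
  check_variant(variant)
  spec <- formula_to_spec(formula, variant, thresholds)
  obs <- build_design(data, spec, variant)
  fit <- dziop_fit(obs, variant, start = start, control = control)
  fit$call <- match.call()
  fit$data <- as.data.frame(data)
  fit
}
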