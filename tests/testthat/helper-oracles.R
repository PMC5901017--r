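# Independent oracles used to validate the probability engine.  Both are
# built from stats::pnorm/dnorm and stats::integrate only, so they share no
# code with the package's bivariate quadrature rule or the GHK simulator.

oracle_pnorm2 <- function(a, b, rho) {
  if (a == Inf) return(pnorm(b))
  if (b == Inf) return(pnorm(a))
  if (a == -Inf || b == -Inf) return(0)
  s <- sqrt(1 - rho^2)
  integrate(function(z) dnorm(z) * pnorm((b - rho * z) / s), -Inf, a,
            rel.tol = 1e-12)$value
}

# trivariate rectangle probability by nested one-dimensional integration
# through the Cholesky representation
oracle_pnorm3 <- function(a, corr) {
  L <- t(chol(corr))
  inner <- function(z1) {
    up2 <- (a[2] - L[2, 1] * z1) / L[2, 2]
    vapply(z1, function(x) {
      u2 <- (a[2] - L[2, 1] * x) / L[2, 2]
      if (u2 < -38) return(0)
      integrate(function(z2)
        dnorm(z2) * pnorm((a[3] - L[3, 1] * x - L[3, 2] * z2) / L[3, 3]),
        -Inf, u2, rel.tol = 1e-10)$value
    }, numeric(1))
  }
  integrate(function(z1) dnorm(z1) * inner(z1), -Inf, a[1] / L[1, 1],
            rel.tol = 1e-9)$value
}

# random positive-definite correlation matrix via partial correlations
random_corr3 <- function() {
  r12 <- tanh(rnorm(1, 0, 0.7))
  r13 <- tanh(rnorm(1, 0, 0.7))
  p23 <- tanh(rnorm(1, 0, 0.7))
  r23 <- r12 * r13 + p23 * sqrt((1 - r12^2) * (1 - r13^2))
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- r12
  m[1, 3] <- m[3, 1] <- r13
  m[2, 3] <- m[3, 2] <- r23
  m
}

# random parameter set + matching small observation set for a variant
random_model <- function(variant, n = 40, J = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n > J)
  dat <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                    z1 = rnorm(n))
  # every category observed, so J is always inferred as intended
  dat$y <- sample(c(0:J, sample(0:J, n - J - 1L, replace = TRUE)))
  has_r <- variant %in% c("ZIOP", "ZIOPC", "DZIOP", "DZIOPC")
  has_m <- variant %in% c("DZIOP", "DZIOPC")
  sp <- equation_spec("y",
                      xr = if (has_r) "x1" else character(),
                      xm = if (has_m) "x2" else character(),
                      xy = "x3",
                      thresholds = if (variant == "GOP") "z1" else character())
  obs <- suppressWarnings(build_design(dat, sp, variant))
  mu <- sort(abs(rnorm(J - 1, 1, 0.5))) + seq(0.1, 0.2, length.out = J - 1)
  rho <- c(0, 0, 0)
  if (variant == "ZIOPC") rho <- c(0, runif(1, -0.8, 0.8), 0)
  if (variant == "DZIOPC") {
    R <- random_corr3()
    rho <- c(R[1, 2], R[1, 3], R[2, 3])
  }
  pa <- parameter_set(variant,
                      beta_r = if (has_r) rnorm(2, 0, 0.7) else numeric(),
                      beta_m = if (has_m) rnorm(2, 0, 0.7) else numeric(),
                      beta_y = rnorm(2, 0, 0.7),
                      mu = mu, rho = rho,
                      gamma = if (variant == "GOP")
                        matrix(rnorm(J - 1, 0, 0.3), J - 1, 1) else NULL)
  list(params = pa, obs = obs, data = dat)
}

# a "dziop" object at known parameters (no estimation), for evaluating
# post-estimation machinery at a chosen point
fit_stub <- function(params, obs, control = dziop_control(se = "none")) {
  skel <- dziop:::param_skeleton(obs, params$variant)
  structure(list(params = params, skel = skel,
                 u = dziop:::pack_params(params, skel),
                 coefficients = dziop:::params_to_theta(params, skel),
                 loglik = NA_real_, n_obs = obs$n, J = obs$J,
                 variant = params$variant, obs = obs, control = control,
                 cov_robust = NULL, cov_hessian = NULL),
            class = "dziop")
}

# DZIOPC starting values at a config's true DZIOP parameters
cfg_to_start <- function(cfg) {
  pa <- cfg$params
  parameter_set("DZIOPC", beta_r = pa$beta_r, beta_m = pa$beta_m,
                beta_y = pa$beta_y, mu = pa$mu, rho = c(0, 0, 0))
}

# warm DZIOPC start from a fitted uncorrelated model
fit_to_corr_start <- function(fit) {
  pa <- fit$params
  parameter_set("DZIOPC", beta_r = pa$beta_r, beta_m = pa$beta_m,
                beta_y = pa$beta_y, mu = pa$mu, rho = c(0, 0, 0))
}

# a small fitted DZIOP model on condensed preset data, shared across tests
cached_fit_env <- new.env(parent = emptyenv())
small_dziop_fit <- function(n = 3000, seed = 5, design = "condensed") {
  key <- paste0("fit_", design, "_", n, "_", seed)
  got <- cached_fit_env[[key]]
  if (!is.null(got)) return(got)
  cfg <- cannabis_preset(design, n = n, seed = seed)
  sim <- simulate_dziop(cfg)
  obs <- build_design(sim$data, cfg$spec, "DZIOP")
  fit <- dziop_fit(obs, "DZIOP", start = cfg$params,
                   control = dziop_control(optimizer = "nlminb"))
  fit$data <- sim$data
  out <- list(fit = fit, sim = sim, cfg = cfg)
  cached_fit_env[[key]] <- out
  out
}
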