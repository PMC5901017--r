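# Parameter container and the unconstrained optimisation parameterisation.
#
# Thresholds: mu_1 = exp(c_1), mu_j = mu_{j-1} + exp(c_j), so any real c
# gives 0 < mu_1 < ... < mu_{J-1} (mu_0 = 0 and mu_J = +Inf are normalised).
# Correlations: rho_rm and rho_ry are 0.99*tanh of free parameters, and the
# third free parameter is the *partial* correlation of (m, y) given r, which
# guarantees a positive-definite Omega_3 for any real values and keeps every
# correlation inside [-0.99, 0.99].

RHO_BOUND <- 0.99

#' Construct and validate a parameter set
#'
#' @param variant one of [dziop_variants()].
#' @param beta_r,beta_m,beta_y coefficient vectors (latent-index units),
#'   including the intercept when the equation has one.
#' @param mu strictly increasing threshold vector of length J-1 with
#'   `mu[1] > 0` (the lowest boundary is normalised to zero).  For GOP these
#'   are the thresholds at threshold-covariate value zero.
#' @param rho named or positional vector `c(rm, ry, my)` of cross-equation
#'   error correlations; must be exactly zero for the uncorrelated variants.
#' @param gamma threshold-equation coefficient matrix, (J-1) x q (GOP only).
#' @return an object of class `"dziop_params"`.
#' @export
parameter_set <- function(variant, beta_r = numeric(), beta_m = numeric(),
                          beta_y = numeric(), mu, rho = c(0, 0, 0),
                          gamma = NULL) {
  check_variant(variant)
  mu <- as.numeric(mu)
  if (length(mu) < 1L) stop("mu must have length J-1 >= 1")
  if (any(diff(c(0, mu)) <= 0))
    stop("thresholds must satisfy 0 < mu[1] < mu[2] < ...")
  rho <- as.numeric(rho)
  if (length(rho) == 1L && variant == "ZIOPC") rho <- c(0, rho, 0)
  if (length(rho) != 3L) stop("rho must be c(rm, ry, my)")
  names(rho) <- c("rm", "ry", "my")
  if (!variant_correlated(variant) && any(rho != 0))
    stop("variant ", variant, " requires all correlations to be exactly 0")
  if (variant == "ZIOPC" && any(rho[c("rm", "my")] != 0))
    stop("ZIOPC admits only the participation-consumption correlation rho_ry")
  if (any(abs(rho) >= 1)) stop("correlations must lie in (-1, 1)")
  if (variant_correlated(variant)) {
    O <- corr3(rho)
    ev <- eigen(O, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10)
      stop("the 3x3 correlation matrix Omega_3 is not positive definite")
  }
  if (variant == "GOP") {
    if (is.null(gamma)) gamma <- matrix(0, length(mu), 0L)
    gamma <- as.matrix(gamma)
    if (nrow(gamma) != length(mu))
      stop("gamma must have one row per threshold")
  } else if (!is.null(gamma) && length(gamma)) {
    stop("gamma is only meaningful for the GOP variant")
  } else gamma <- NULL
  if (!variant_has_r(variant) && length(beta_r))
    stop("variant ", variant, " has no participation equation")
  if (!variant_has_m(variant) && length(beta_m))
    stop("variant ", variant, " has no misreporting equation")
  structure(list(variant = variant,
                 beta_r = as.numeric(beta_r), beta_m = as.numeric(beta_m),
                 beta_y = as.numeric(beta_y), mu = mu, rho = rho,
                 gamma = gamma),
            class = "dziop_params")
}

# full 3x3 correlation matrix of (eps_r, eps_m, eps_y)
corr3 <- function(rho) {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- rho[["rm"]]
  R[1, 3] <- R[3, 1] <- rho[["ry"]]
  R[2, 3] <- R[3, 2] <- rho[["my"]]
  R
}

#' @export
print.dziop_params <- function(x, ...) {
  cat("dziop parameter set, variant", x$variant, "\n")
  if (length(x$beta_r)) cat("  beta_r:", signif(x$beta_r, 4), "\n")
  if (length(x$beta_m)) cat("  beta_m:", signif(x$beta_m, 4), "\n")
  cat("  beta_y:", signif(x$beta_y, 4), "\n")
  cat("  mu:    ", signif(x$mu, 4), "\n")
  if (variant_correlated(x$variant))
    cat("  rho:   ", paste(names(x$rho), signif(x$rho, 4), collapse = ", "), "\n")
  if (!is.null(x$gamma) && ncol(x$gamma))
    cat("  gamma: ", signif(as.vector(t(x$gamma)), 4), "\n")
  invisible(x)
}

# --- skeleton: dimensions + name bookkeeping for one model ----------------

param_skeleton <- function(obs, variant) {
  check_variant(variant)
  kr <- if (variant_has_r(variant)) ncol(obs$Xr) else 0L
  km <- if (variant_has_m(variant)) ncol(obs$Xm) else 0L
  ky <- ncol(obs$Xy)
  if (variant_has_r(variant) && kr == 0L)
    stop("variant ", variant, " needs a non-empty participation equation")
  if (variant_has_m(variant) && km == 0L)
    stop("variant ", variant, " needs a non-empty misreporting equation")
  if (ky == 0L) stop("the consumption equation is empty")
  qt <- if (variant == "GOP") ncol(obs$Zt) else 0L
  nrho <- if (variant == "DZIOPC") 3L else if (variant == "ZIOPC") 1L else 0L
  J <- obs$J
  nm <- c(if (kr) paste0("r:", colnames(obs$Xr)),
          if (km) paste0("m:", colnames(obs$Xm)),
          paste0("y:", colnames(obs$Xy)),
          paste0("mu_", seq_len(J - 1L)),
          if (qt) as.vector(t(outer(seq_len(J - 1L), colnames(obs$Zt),
                                    function(j, v) paste0("thr", j, ":", v)))),
          if (nrho == 3L) c("rho_rm", "rho_ry", "rho_my"),
          if (nrho == 1L) "rho_ry")
  list(variant = variant, kr = kr, km = km, ky = ky, J = J, qt = qt,
       nrho = nrho, npar = kr + km + ky + (J - 1L) + qt * (J - 1L) + nrho,
       names = nm)
}

# unconstrained vector -> dziop_params
unpack_params <- function(u, skel) {
  i <- 0L
  take <- function(k) {
    if (k == 0L) return(numeric(0))
    out <- u[(i + 1L):(i + k)]
    i <<- i + k
    out
  }
  beta_r <- take(skel$kr)
  beta_m <- take(skel$km)
  beta_y <- take(skel$ky)
  cthr <- take(skel$J - 1L)
  mu <- cumsum(exp(cthr))
  gamma <- NULL
  if (skel$variant == "GOP")
    gamma <- matrix(take(skel$qt * (skel$J - 1L)), nrow = skel$J - 1L,
                    byrow = TRUE)
  rho <- c(rm = 0, ry = 0, my = 0)
  if (skel$nrho == 1L) {
    rho[["ry"]] <- RHO_BOUND * tanh(take(1L))
  } else if (skel$nrho == 3L) {
    z <- take(3L)
    rho[["rm"]] <- RHO_BOUND * tanh(z[1L])
    rho[["ry"]] <- RHO_BOUND * tanh(z[2L])
    pmy <- RHO_BOUND * tanh(z[3L])   # partial corr of (m, y) given r
    rho[["my"]] <- rho[["rm"]] * rho[["ry"]] +
      pmy * sqrt((1 - rho[["rm"]]^2) * (1 - rho[["ry"]]^2))
  }
  parameter_set(skel$variant, beta_r, beta_m, beta_y, mu, rho, gamma)
}

# dziop_params -> unconstrained vector
pack_params <- function(params, skel) {
  stopifnot(params$variant == skel$variant)
  cthr <- log(diff(c(0, params$mu)))
  rho_u <- numeric(0)
  if (skel$nrho == 1L) {
    rho_u <- atanh(params$rho[["ry"]] / RHO_BOUND)
  } else if (skel$nrho == 3L) {
    r12 <- params$rho[["rm"]]; r13 <- params$rho[["ry"]]
    pmy <- (params$rho[["my"]] - r12 * r13) /
      sqrt((1 - r12^2) * (1 - r13^2))
    if (abs(pmy) >= RHO_BOUND) pmy <- sign(pmy) * (RHO_BOUND - 1e-6)
    rho_u <- atanh(c(r12, r13, pmy) / RHO_BOUND)
  }
  gam <- if (skel$variant == "GOP" && !is.null(params$gamma))
    as.vector(t(params$gamma)) else numeric(0)
  u <- c(params$beta_r, params$beta_m, params$beta_y, cthr, gam, rho_u)
  if (length(u) != skel$npar)
    stop("parameter dimensions do not match the design ",
         sprintf("(got %d, expected %d)", length(u), skel$npar))
  u
}

# reported (constrained) parameter vector with names
params_to_theta <- function(params, skel) {
  th <- c(params$beta_r, params$beta_m, params$beta_y, params$mu,
          if (skel$variant == "GOP" && skel$qt) as.vector(t(params$gamma)),
          if (skel$nrho == 3L) unname(params$rho),
          if (skel$nrho == 1L) unname(params$rho[["ry"]]))
  names(th) <- skel$names
  th
}

# reported vector back into a parameter set (for delta-method Jacobians)
theta_to_params <- function(theta, skel) {
  i <- 0L
  take <- function(k) {
    if (k == 0L) return(numeric(0))
    out <- theta[(i + 1L):(i + k)]
    i <<- i + k
    out
  }
  beta_r <- take(skel$kr); beta_m <- take(skel$km); beta_y <- take(skel$ky)
  mu <- take(skel$J - 1L)
  gamma <- NULL
  if (skel$variant == "GOP")
    gamma <- matrix(take(skel$qt * (skel$J - 1L)), nrow = skel$J - 1L,
                    byrow = TRUE)
  rho <- c(rm = 0, ry = 0, my = 0)
  if (skel$nrho == 3L) rho[] <- take(3L)
  if (skel$nrho == 1L) rho[["ry"]] <- take(1L)
  parameter_set(skel$variant, beta_r, beta_m, beta_y, mu, rho, gamma)
}
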