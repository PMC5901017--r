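# Category probabilities for all model variants.
#
# Zeros in the double-inflated model arise from three sources:
#   nonparticipation        P(r = 0)
#   participant misreporter P(r = 1, m = 0)
#   truthful zero consumer  P(r = 1, m = 1, ytilde = 0)
# With independent errors these are products of univariate probits; with
# correlated errors they are rectangle probabilities of the transformed
# vector (-eps_r, -eps_m, eps_y), evaluated either in closed form (bivariate,
# ZIOPC) or by one recursive GHK pass (trivariate, DZIOPC) whose terms share
# the conditioning factors, so each row's probabilities sum to one exactly.

PROB_FLOOR <- 1e-300

# quasi-random draw bundle reused across likelihood evaluations
ghk_draws <- function(n, n_draws, seed, antithetic = TRUE) {
  m <- if (antithetic) as.integer(ceiling(n_draws / 2)) else as.integer(n_draws)
  sh <- halton_shifts(seed)
  list(m = m,
       u1 = cpp_halton(n * m, 2L, sh[1], 0L),
       u2 = cpp_halton(n * m, 3L, sh[2], 0L),
       antithetic = antithetic, n = n, n_draws = n_draws, seed = seed)
}

linear_indices <- function(params, obs) {
  skel_check_dims(params, obs)
  list(ar = if (length(params$beta_r)) drop(obs$Xr %*% params$beta_r) else NULL,
       am = if (length(params$beta_m)) drop(obs$Xm %*% params$beta_m) else NULL,
       ay = drop(obs$Xy %*% params$beta_y))
}

skel_check_dims <- function(params, obs) {
  v <- params$variant
  if (variant_has_r(v) && length(params$beta_r) != ncol(obs$Xr))
    stop("beta_r length does not match the participation design")
  if (variant_has_m(v) && length(params$beta_m) != ncol(obs$Xm))
    stop("beta_m length does not match the misreporting design")
  if (length(params$beta_y) != ncol(obs$Xy))
    stop("beta_y length does not match the consumption design")
  if (length(params$mu) != obs$J - 1L)
    stop("mu must have length J-1 = ", obs$J - 1L)
  if (v == "GOP" && (is.null(params$gamma) || ncol(params$gamma) != ncol(obs$Zt)))
    stop("gamma columns do not match the threshold design")
  invisible(TRUE)
}

# n x (J-1) matrix of row-level thresholds (GOP) or a recycled constant row
threshold_matrix <- function(params, obs) {
  J <- obs$J
  if (params$variant == "GOP" && ncol(obs$Zt)) {
    d <- diff(c(0, params$mu))                 # positive increments
    M <- sweep(exp(obs$Zt %*% t(params$gamma)), 2, d, `*`)
    if (J > 2L)
      for (j in 2:(J - 1L)) M[, j] <- M[, j] + M[, j - 1L]
    M
  } else {
    matrix(params$mu, obs$n, J - 1L, byrow = TRUE)
  }
}

# core computation: list(probs = n x (J+1), comps = n x 3)
compute_probs <- function(params, obs, n_draws = 500L, seed = 1L,
                          antithetic = TRUE, draws = NULL) {
  v <- params$variant
  J <- obs$J
  n <- obs$n
  li <- linear_indices(params, obs)
  ay <- li$ay
  if (v == "DZIOPC") {
    if (is.null(draws)) draws <- ghk_draws(n, n_draws, seed, antithetic)
    R <- signed_corr3(params$rho[["rm"]], params$rho[["ry"]],
                      params$rho[["my"]], c(-1, -1, 1))
    L <- check_corr3(R)
    out <- cpp_ghk_dziopc(li$ar, li$am, ay, params$mu, L, draws$m,
                          draws$u1, draws$u2, draws$antithetic, integer(0))
    probs <- out[, 1:(J + 1L), drop = FALSE]
    comps <- out[, (J + 2L):(J + 4L), drop = FALSE]
  } else {
    thr <- threshold_matrix(params, obs)
    # cumulative consumption probabilities P(ytilde <= j), j = 0..J-1
    cum <- cbind(pnorm(-ay), pnorm(thr - ay))
    pr <- if (variant_has_r(v)) pnorm(li$ar) else rep(1, n)
    pm <- if (variant_has_m(v)) pnorm(li$am) else rep(1, n)
    if (v == "ZIOPC") {
      # P(r=1, ytilde <= j) = P(-eps_r <= ar, eps_y <= c) with corr -rho_ry
      cum_joint <- cbind(
        pnorm2(li$ar, -ay, -params$rho[["ry"]]),
        vapply(seq_len(J - 1L),
               function(j) pnorm2(li$ar, params$mu[j] - ay,
                                  -params$rho[["ry"]]),
               numeric(n)))
    } else {
      cum_joint <- pr * pm * cum
    }
    comps <- cbind(1 - pr,                    # nonparticipation
                   pr * (1 - pm),             # participant misreporting
                   cum_joint[, 1L])           # truthful zero consumption
    probs <- matrix(0, n, J + 1L)
    probs[, 1L] <- rowSums(comps)
    if (J > 1L)
      for (j in seq_len(J - 1L))
        probs[, j + 1L] <- cum_joint[, j + 1L] - cum_joint[, j]
    probs[, J + 1L] <- pr * pm - cum_joint[, J]
  }
  bad <- probs < -1e-8 | probs > 1 + 1e-8
  if (any(bad))
    stop("internal consistency failure: category probability outside [0, 1] (",
         signif(probs[which(bad)[1]], 4), ")")
  probs <- pmin(pmax(probs, 0), 1)
  comps <- pmin(pmax(comps, 0), 1)
  colnames(probs) <- paste0("p", 0:J)
  colnames(comps) <- c("nonparticipation", "misreporting", "zero_consumption")
  list(probs = probs, comps = comps)
}

#' Category probabilities under a parameter set
#'
#' Evaluates, for every row of the observation set, the probability of each
#' outcome category 0..J implied by the model variant of \code{params}.  For
#' the correlated double-inflated variant (DZIOPC) the trivariate rectangle
#' probabilities are evaluated with the GHK simulator using antithetic
#' scrambled Halton draws; all terms for a row share one recursive pass, so
#' rows sum to one exactly.
#'
#' @param params a [parameter_set()].
#' @param obs a [build_design()] observation set.
#' @param n_draws,seed,antithetic GHK settings (DZIOPC only).
#' @param draws optional precomputed draw bundle (internal use).
#' @return an n x (J+1) matrix of probabilities; rows sum to 1.
#' @examples
#' d <- data.frame(y = c(0, 1, 2, 3), x = c(0, 0, 0, 0))
#' sp <- equation_spec("y", xr = "x", xm = "x", xy = "x")
#' ob <- build_design(d, sp)
#' pa <- parameter_set("DZIOP", beta_r = c(0, 0), beta_m = c(0, 0),
#'                     beta_y = c(0, 0), mu = c(0.8, 1.6))
#' category_probs(pa, ob)[1, ]   # P(y=0) = 0.5 + 0.25 + 0.125 = 0.875
#' @export
category_probs <- function(params, obs, n_draws = 500L, seed = 1L,
                           antithetic = TRUE, draws = NULL) {
  compute_probs(params, obs, n_draws, seed, antithetic, draws)$probs
}

#' Decompose the zero probability into its three sources
#'
#' Returns the per-row probabilities of the three latent origins of an
#' observed zero: nonparticipation, participant misreporting, and truthful
#' zero consumption.  The three columns sum to the model's P(y = 0).
#'
#' @inheritParams category_probs
#' @return an n x 3 matrix with columns `nonparticipation`, `misreporting`,
#'   `zero_consumption`.
#' @export
zero_components <- function(params, obs, n_draws = 500L, seed = 1L,
                            antithetic = TRUE, draws = NULL) {
  if (!variant_has_m(params$variant))
    stop("zero_components needs a variant with a misreporting equation ",
         "(DZIOP or DZIOPC), not ", params$variant)
  compute_probs(params, obs, n_draws, seed, antithetic, draws)$comps
}

# fast path: probability of the observed category only (per row)
observed_probs <- function(params, obs, draws = NULL, n_draws = 500L,
                           seed = 1L, antithetic = TRUE) {
  if (params$variant == "DZIOPC") {
    li <- linear_indices(params, obs)
    if (is.null(draws)) draws <- ghk_draws(obs$n, n_draws, seed, antithetic)
    R <- signed_corr3(params$rho[["rm"]], params$rho[["ry"]],
                      params$rho[["my"]], c(-1, -1, 1))
    L <- check_corr3(R)
    as.vector(cpp_ghk_dziopc(li$ar, li$am, li$ay, params$mu, L, draws$m,
                             draws$u1, draws$u2, draws$antithetic,
                             as.integer(obs$y)))
  } else {
    p <- compute_probs(params, obs)$probs
    p[cbind(seq_len(obs$n), obs$y + 1L)]
  }
}
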