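#' @useDynLib dziop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pnorm qnorm dnorm integrate
NULL

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch
gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  A <- matrix(0, n, n)
  A[cbind(i, i + 1)] <- b
  A[cbind(i + 1, i)] <- b
  e <- eigen(A, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = 2 * e$vectors[1, ord]^2)
}

# composite rule on (0, 1): fractions and weights, panels x nodes
.gl_cache <- new.env(parent = emptyenv())
gl_composite01 <- function(panels = 4L, nodes = 20L) {
  key <- paste0(panels, "_", nodes)
  got <- .gl_cache[[key]]
  if (!is.null(got)) return(got)
  gl <- gauss_legendre(nodes)
  frac <- as.vector(outer((gl$nodes + 1) / (2 * panels),
                          (seq_len(panels) - 1) / panels, `+`))
  wt <- rep(gl$weights / (2 * panels), panels)
  out <- list(frac = frac, wt = wt)
  .gl_cache[[key]] <- out
  out
}

#' Bivariate standard normal distribution function
#'
#' Computes \eqn{P(Z_1 \le a, Z_2 \le b)} for a standardised bivariate normal
#' vector with correlation \code{rho}, using Gauss-Legendre quadrature on the
#' Drezner-Wesolowsky angular representation
#' \deqn{\Phi_2(a,b;\rho) = \Phi(a)\Phi(b) + \frac{1}{2\pi}
#'   \int_0^{\arcsin\rho} \exp\!\Big(-\frac{a^2+b^2-2ab\sin\theta}
#'   {2\cos^2\theta}\Big)\, d\theta,}
#' which is smooth in \eqn{\theta} for all \eqn{|\rho|<1}.  Absolute accuracy
#' is on the order of 1e-14 over the admissible correlation range.
#'
#' @param a,b upper integration limits; may be \code{-Inf}/\code{Inf};
#'   recycled to a common length.
#' @param rho correlation in (-1, 1); scalar or recycled.
#' @return vector of probabilities in \code{[0, 1]}.
#' @examples
#' pnorm2(0, 0, 0.5)       # 1/4 + asin(0.5)/(2*pi) = 1/3
#' pnorm2(1.3, Inf, -0.4)  # marginalises to pnorm(1.3)
#' @export
pnorm2 <- function(a, b, rho = 0) {
  n <- max(length(a), length(b), length(rho))
  a <- rep_len(a, n); b <- rep_len(b, n); rho <- rep_len(rho, n)
  if (any(abs(rho) >= 1))
    stop("pnorm2: correlation must lie strictly inside (-1, 1)")
  if (any(is.na(a) | is.na(b) | is.na(rho)))
    stop("pnorm2: missing values in arguments")
  out <- numeric(n)
  # infinite limits reduce to marginals / zero
  neg <- (a == -Inf) | (b == -Inf)
  out[neg] <- 0
  ok <- !neg
  pa <- pnorm(a); pb <- pnorm(b)
  plain <- ok & (a == Inf | b == Inf | rho == 0)
  out[plain] <- ifelse(a[plain] == Inf, pb[plain],
                ifelse(b[plain] == Inf, pa[plain],
                       pa[plain] * pb[plain]))
  gen <- ok & !plain
  if (any(gen)) {
    ag <- a[gen]; bg <- b[gen]; rg <- rho[gen]
    panels <- if (max(abs(rg)) > 0.925) 8L else 4L
    gl <- gl_composite01(panels, 20L)
    s <- asin(rg)
    theta <- outer(s, gl$frac)                 # n x K
    sn <- sin(theta)
    cs2 <- cos(theta)^2
    f <- exp(-((ag^2 + bg^2) - 2 * ag * bg * sn) / (2 * cs2))
    val <- pa[gen] * pb[gen] + (s / (2 * pi)) * as.vector(f %*% gl$wt)
    out[gen] <- pmin(1, pmax(0, val))
  }
  out
}

# conditional correlation of (2,3) given 1 for a 3x3 correlation matrix
cond_corr23 <- function(corr) {
  s2 <- sqrt(1 - corr[1, 2]^2)
  s3 <- sqrt(1 - corr[1, 3]^2)
  (corr[2, 3] - corr[1, 2] * corr[1, 3]) / (s2 * s3)
}

check_corr3 <- function(corr) {
  if (!is.matrix(corr) || any(dim(corr) != 3L))
    stop("corr must be a 3x3 correlation matrix")
  if (max(abs(corr - t(corr))) > 1e-10 || max(abs(diag(corr) - 1)) > 1e-10)
    stop("corr must be symmetric with unit diagonal")
  L <- tryCatch(t(chol(corr)), error = function(e)
    stop("corr is not positive definite (Cholesky failed): ",
         conditionMessage(e), call. = FALSE))
  L
}

# quadrature evaluation of the trivariate CDF: condition on component 1 and
# integrate the conditional bivariate CDF against the normal density
ptrivariate_quad <- function(upper, corr, rel.tol = 1e-10) {
  a <- upper
  if (any(a == -Inf)) return(0)
  if (a[1] == Inf) return(pnorm2(a[2], a[3], corr[2, 3]))
  if (a[2] == Inf) return(pnorm2(a[1], a[3], corr[1, 3]))
  if (a[3] == Inf) return(pnorm2(a[1], a[2], corr[1, 2]))
  s2 <- sqrt(1 - corr[1, 2]^2)
  s3 <- sqrt(1 - corr[1, 3]^2)
  r23 <- cond_corr23(corr)
  f <- function(z)
    dnorm(z) * pnorm2((a[2] - corr[1, 2] * z) / s2,
                      (a[3] - corr[1, 3] * z) / s3, r23)
  integrate(f, -Inf, a[1], rel.tol = rel.tol, abs.tol = 1e-13)$value
}

# deterministic scramble shifts derived from an integer seed (golden-ratio
# style rotation; leaves the global RNG stream untouched)
halton_shifts <- function(seed) {
  (abs(as.numeric(seed)) * c(0.6180339887498949, 0.7548776662466927) +
     c(0.1359549995793928, 0.3819660112501051)) %% 1
}

#' GHK simulated probability of a trivariate normal rectangle
#'
#' Recursive importance-sampling (Geweke-Hajivassiliou-Keane) estimate of
#' \eqn{P(Z_1 \le a_1, Z_2 \le a_2, Z_3 \le a_3)} for \eqn{Z \sim N(0, R)}.
#' Uses antithetic, randomly shifted Halton draws (bases 2 and 3); the shift
#' is a deterministic function of \code{seed}, so results are reproducible
#' and smooth in the limits, which is what the simulated likelihood needs.
#'
#' @param upper numeric vector of three upper limits, or an n x 3 matrix of
#'   row-wise limits; entries may be infinite.
#' @param corr 3 x 3 positive-definite correlation matrix.
#' @param n_draws total number of draws per row (antithetic pairs count as
#'   two draws).
#' @param seed integer governing the Halton scramble.
#' @param antithetic use antithetic pairing (default \code{TRUE}).
#' @param segment_rows give each row its own Halton segment (default); with
#'   \code{FALSE} all rows share one segment.
#' @return vector of probabilities with attribute \code{"se"}, a draw-based
#'   standard error (conservative for quasi-random draws).
#' @examples
#' ghk_rect_prob(c(0, 0, 0), diag(3), n_draws = 2000, seed = 1)  # ~ 0.125
#' @export
ghk_rect_prob <- function(upper, corr, n_draws = 500L, seed = 1L,
                          antithetic = TRUE, segment_rows = TRUE) {
  if (is.null(dim(upper))) upper <- matrix(upper, nrow = 1)
  if (ncol(upper) != 3L) stop("upper must have three columns")
  if (n_draws < 1L) stop("n_draws must be at least 1")
  L <- check_corr3(corr)
  m <- if (antithetic) as.integer(ceiling(n_draws / 2)) else as.integer(n_draws)
  sh <- halton_shifts(seed)
  res <- cpp_ghk_rect(upper, L, m, sh[1], sh[2], antithetic, segment_rows)
  out <- res$prob
  attr(out, "se") <- res$se
  out
}

#' Trivariate standard normal distribution function
#'
#' \eqn{P(Z_1 \le a_1, Z_2 \le a_2, Z_3 \le a_3)} for a standardised
#' trivariate normal with correlation matrix \code{corr}, either by the GHK
#' simulator (see [ghk_rect_prob()]) or by deterministic adaptive quadrature
#' that integrates the conditional bivariate CDF over the first component.
#'
#' @inheritParams ghk_rect_prob
#' @param method `"quadrature"` (deterministic, default) or `"ghk"`.
#' @return vector of probabilities (one per row of \code{upper}).
#' @export
pnorm3 <- function(upper, corr, method = c("quadrature", "ghk"),
                   n_draws = 500L, seed = 1L) {
  method <- match.arg(method)
  if (is.null(dim(upper))) upper <- matrix(upper, nrow = 1)
  if (ncol(upper) != 3L) stop("upper must have three columns")
  check_corr3(corr)
  if (method == "ghk")
    return(as.vector(ghk_rect_prob(upper, corr, n_draws = n_draws,
                                   seed = seed)))
  vapply(seq_len(nrow(upper)),
         function(i) ptrivariate_quad(upper[i, ], corr), numeric(1))
}

# Signed-region probabilities --------------------------------------------
#
# All model formulas are derived from one primitive:
#   P(s1 e1 <= a1, s2 e2 <= a2, s3 e3 <= a3),  e ~ N(0, Omega3),
# which is a plain rectangle probability for the sign-adjusted correlations
# rho'_kl = s_k s_l rho_kl.  Negating an argument therefore negates that
# dimension's correlations, the convention the category probabilities rely
# on.

signed_corr3 <- function(rho_rm, rho_ry, rho_my, signs) {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- signs[1] * signs[2] * rho_rm
  R[1, 3] <- R[3, 1] <- signs[1] * signs[3] * rho_ry
  R[2, 3] <- R[3, 2] <- signs[2] * signs[3] * rho_my
  R
}
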