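neutral_model <- function(variant = "DZIOP", rho = c(0, 0, 0)) {
  d <- data.frame(y = c(0L, 1L, 2L, 3L), x = 0)
  sp <- equation_spec("y", xr = "x", xm = "x", xy = "x")
  obs <- suppressWarnings(build_design(d, sp))
  pa <- parameter_set(variant, beta_r = c(0, 0), beta_m = c(0, 0),
                      beta_y = c(0, 0), mu = c(0.8, 1.6), rho = rho)
  list(params = pa, obs = obs)
}

test_that("zero-probability hand evaluation: all indices at zero", {
  m <- neutral_model()
  p <- category_probs(m$params, m$obs)
  # 0.5 + 0.5*0.5 + 0.5*0.5*0.5
  expect_equal(unname(p[1, 1]), 0.875, tolerance = 1e-12)
  cc <- zero_components(m$params, m$obs)
  expect_equal(unname(cc[1, ]), c(0.5, 0.25, 0.125), tolerance = 1e-12)
  expect_equal(rowSums(cc), unname(p[, 1]), tolerance = 1e-12)
})

test_that("degenerate hurdles collapse to the plain ordered probit", {
  d <- data.frame(y = c(0L, 1L, 2L, 3L), x = rnorm(4))
  sp <- equation_spec("y", xr = "x", xm = "x", xy = "x")
  obs <- suppressWarnings(build_design(d, sp))
  spo <- equation_spec("y", xy = "x")
  obso <- build_design(d, spo, "OP")
  mu <- c(0.8, 1.6)
  by <- c(0.2, 0.5)
  pa <- parameter_set("DZIOP", beta_r = c(10, 0), beta_m = c(10, 0),
                      beta_y = by, mu = mu)
  po <- parameter_set("OP", beta_y = by, mu = mu)
  expect_equal(category_probs(pa, obs), category_probs(po, obso),
               tolerance = 1e-8, ignore_attr = TRUE)
  # participation and truthful reporting certain: zeros all from consumption
  cc <- zero_components(pa, obs)
  expect_equal(unname(cc[, 1]), rep(0, 4), tolerance = 1e-8)
  expect_equal(unname(cc[, 2]), rep(0, 4), tolerance = 1e-8)
  expect_equal(unname(cc[, 3]), pnorm(-obs$Xy %*% by)[, 1], tolerance = 1e-8)
})

test_that("category probabilities sum to one across variants", {
  set.seed(42)
  for (variant in dziop_variants()) {
    for (k in 1:25) {
      m <- random_model(variant, n = 30)
      p <- category_probs(m$params, m$obs, n_draws = 64, seed = k)
      expect_true(all(p >= 0 & p <= 1))
      tol <- if (variant == "DZIOPC") 1e-6 else 1e-10
      expect_lt(max(abs(rowSums(p) - 1)), tol)
    }
  }
})

test_that("correlated variants nest their uncorrelated counterparts", {
  set.seed(9)
  m <- random_model("DZIOP", n = 50)
  pa0 <- m$params
  pac <- parameter_set("DZIOPC", beta_r = pa0$beta_r, beta_m = pa0$beta_m,
                       beta_y = pa0$beta_y, mu = pa0$mu, rho = c(0, 0, 0))
  # GHK is exact at zero correlation, so agreement is to machine precision
  expect_equal(category_probs(pac, m$obs, n_draws = 64, seed = 1),
               category_probs(pa0, m$obs), tolerance = 1e-12)
  # ZIOPC at rho = 0 equals ZIOP
  mz <- random_model("ZIOP", n = 50)
  paz <- mz$params
  pazc <- parameter_set("ZIOPC", beta_r = paz$beta_r, beta_y = paz$beta_y,
                        mu = paz$mu, rho = 0)
  expect_equal(category_probs(pazc, mz$obs), category_probs(paz, mz$obs),
               tolerance = 1e-10)
  # DZIOP with certain truthful reporting equals ZIOP
  mD <- random_model("DZIOP", n = 50)
  paD <- mD$params
  paD2 <- parameter_set("DZIOP", beta_r = paD$beta_r, beta_m = c(20, 0),
                        beta_y = paD$beta_y, mu = paD$mu)
  obZ <- mD$obs
  paZ <- parameter_set("ZIOP", beta_r = paD$beta_r, beta_y = paD$beta_y,
                       mu = paD$mu)
  obZ2 <- mD$obs
  obZ2$Xm <- obZ2$Xm[, 0, drop = FALSE]
  expect_equal(category_probs(paD2, mD$obs), category_probs(paZ, obZ2),
               tolerance = 1e-8)
})

test_that("correlated category probabilities match a brute-force region count", {
  # the signed-region convention: every region probability in the y = 0
  # decomposition and the positive categories is validated against direct
  # Monte-Carlo simulation of the latent system
  set.seed(31)
  for (k in 1:4) {
    R <- random_corr3()
    rho <- c(rm = R[1, 2], ry = R[1, 3], my = R[2, 3])
    d <- data.frame(y = 0:3, x1 = rnorm(4), x2 = rnorm(4), x3 = rnorm(4))
    sp <- equation_spec("y", xr = "x1", xm = "x2", xy = "x3")
    obs <- suppressWarnings(build_design(d, sp))
    pa <- parameter_set("DZIOPC", beta_r = rnorm(2, 0, 0.5),
                        beta_m = rnorm(2, 0, 0.5),
                        beta_y = rnorm(2, 0, 0.5),
                        mu = c(0.8, 1.6), rho = rho)
    p <- category_probs(pa, obs, n_draws = 4000, seed = k)
    cc <- zero_components(pa, obs, n_draws = 4000, seed = k)
    # brute-force draw of the latent system
    N <- 4e5
    L <- t(chol(R))
    eps <- matrix(rnorm(3 * N), N, 3) %*% t(L)
    ar <- drop(obs$Xr %*% pa$beta_r)
    am <- drop(obs$Xm %*% pa$beta_m)
    ay <- drop(obs$Xy %*% pa$beta_y)
    for (i in 1:2) {
      r <- ar[i] + eps[, 1] > 0
      m <- am[i] + eps[, 2] > 0
      yt <- findInterval(ay[i] + eps[, 3], c(0, pa$mu), left.open = TRUE)
      ysim <- r * m * yt
      emp <- tabulate(ysim + 1L, nbins = 4L) / N
      mcse <- sqrt(emp * (1 - emp) / N)
      expect_true(all(abs(p[i, ] - emp) < 4 * pmax(mcse, 2e-3)))
      emp_c <- c(mean(!r), mean(r & !m), mean(r & m & yt == 0))
      expect_true(all(abs(cc[i, ] - emp_c) < 4 * pmax(sqrt(emp_c * (1 - emp_c) / N), 2e-3)))
    }
  }
})

test_that("GOP thresholds stay ordered for any coefficients", {
  set.seed(17)
  for (k in 1:20) {
    m <- random_model("GOP", n = 30)
    thr <- dziop:::threshold_matrix(m$params, m$obs)
    expect_true(all(thr[, 1] > 0))
    if (ncol(thr) > 1)
      expect_true(all(diff(t(thr)) > 0))
    p <- category_probs(m$params, m$obs)
    expect_lt(max(abs(rowSums(p) - 1)), 1e-10)
  }
})

test_that("dimension mismatches and wrong variants raise errors", {
  m <- neutral_model()
  bad <- parameter_set("DZIOP", beta_r = c(0, 0, 0), beta_m = c(0, 0),
                       beta_y = c(0, 0), mu = c(0.8, 1.6))
  expect_error(category_probs(bad, m$obs), "beta_r")
  mz <- random_model("ZIOP", n = 10, seed = 1)
  expect_error(zero_components(mz$params, mz$obs), "misreporting")
})
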