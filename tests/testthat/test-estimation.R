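test_that("log-likelihood matches hand evaluation and is additive", {
  d <- data.frame(y = 0L, x = 0)
  sp <- equation_spec("y", xr = "x", xm = "x", xy = "x")
  obs <- suppressWarnings(build_design(rbind(d, data.frame(y = 2L, x = 0),
                                             data.frame(y = 3L, x = 0)),
                                       sp))
  obs1 <- dziop:::subset_obs(obs, c(TRUE, FALSE, FALSE))
  pa <- parameter_set("DZIOP", beta_r = c(0, 0), beta_m = c(0, 0),
                      beta_y = c(0, 0), mu = c(0.8, 1.6))
  expect_equal(loglik(pa, obs1), log(0.875), tolerance = 1e-10)
  # additivity over rows
  parts <- vapply(1:3, function(i)
    loglik(pa, dziop:::subset_obs(obs, seq_len(3) == i)), numeric(1))
  expect_equal(loglik(pa, obs), sum(parts), tolerance = 1e-10)
  # duplicating every row doubles the log-likelihood
  obs2 <- dziop:::subset_obs(obs, rep(TRUE, 3))
  obs_dup <- dziop:::subset_obs(obs, c(1, 1, 2, 2, 3, 3) * 0 + TRUE)
  idx <- rep(1:3, each = 2)
  obs_dup <- list(y = obs$y[idx], n = 6L, J = obs$J,
                  Xr = obs$Xr[idx, , drop = FALSE],
                  Xm = obs$Xm[idx, , drop = FALSE],
                  Xy = obs$Xy[idx, , drop = FALSE],
                  Zt = obs$Zt[idx, , drop = FALSE], spec = obs$spec)
  class(obs_dup) <- "dziop_obs"
  expect_equal(loglik(pa, obs_dup), 2 * loglik(pa, obs), tolerance = 1e-10)
})

test_that("starting values honour their contracts", {
  set.seed(61)
  cfg <- cannabis_preset("condensed", n = 1500, seed = 8)
  sim <- simulate_dziop(cfg)
  obs <- build_design(sim$data, cfg$spec, "DZIOP")
  for (variant in c("OP", "ZIOP", "DZIOP", "DZIOPC")) {
    st <- starting_values(obs, variant)
    expect_s3_class(st, "dziop_params")
    expect_true(all(diff(c(0, st$mu)) > 0))
    if (variant == "DZIOPC") expect_equal(unname(st$rho), c(0, 0, 0))
  }
  # DZIOPC start equals DZIOP start apart from the zero correlations
  sd1 <- starting_values(obs, "DZIOP")
  sd2 <- starting_values(obs, "DZIOPC")
  expect_equal(sd1$beta_r, sd2$beta_r)
  expect_equal(sd1$beta_y, sd2$beta_y)
  expect_equal(sd1$mu, sd2$mu)
})

test_that("the ordered-probit fit agrees with an independent implementation", {
  skip_if_not_installed("MASS")
  set.seed(19)
  n <- 1200
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  ystar <- 0.8 * d$x1 - 0.5 * d$x2 + rnorm(n)
  d$y <- as.integer(findInterval(ystar, c(-0.5, 0.5, 1.3)))
  obs <- build_design(d, equation_spec("y", xy = c("x1", "x2")), "OP")
  fit <- dziop_fit(obs, "OP", control = dziop_control(se = "none"))
  pol <- MASS::polr(factor(y) ~ x1 + x2, data = d, method = "probit")
  # same slopes; polr's cutpoints map to intercept + thresholds with mu0 = 0
  expect_equal(unname(fit$params$beta_y[2:3]), unname(coef(pol)),
               tolerance = 1e-3)
  zeta <- unname(pol$zeta)
  expect_equal(unname(fit$params$beta_y[1]), -zeta[1], tolerance = 1e-3)
  expect_equal(unname(fit$params$mu), zeta[2:3] - zeta[1], tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(logLik(pol)), tolerance = 1e-6)
})

test_that("fitting improves on the start and recovers a simulated DGP", {
  sh <- small_dziop_fit()
  fit <- sh$fit
  cfg <- sh$cfg
  expect_true(fit$converged)
  st_ll <- loglik(cfg$params, fit$obs)
  expect_gte(fit$loglik, st_ll)
  truth <- c(cfg$params$beta_r, cfg$params$beta_m, cfg$params$beta_y,
             cfg$params$mu)
  se <- sqrt(diag(fit$cov_robust))
  expect_true(all(abs(coef(fit) - truth) < 4 * se))
})

test_that("identical options and seed give bit-identical fits", {
  set.seed(77)
  cfg <- cannabis_preset("minimal", n = 500, seed = 3)
  sim <- simulate_dziop(cfg)
  obs <- build_design(sim$data, cfg$spec, "DZIOPC")
  ctrl <- dziop_control(se = "none", n_draws = 48, seed = 5,
                        optimizer = "nlminb", max_iter = 30)
  f1 <- dziop_fit(obs, "DZIOPC", start = cfg_to_start(cfg), control = ctrl)
  f2 <- dziop_fit(obs, "DZIOPC", start = cfg_to_start(cfg), control = ctrl)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(coef(f1), coef(f2))
})

test_that("a DZIOP fit on OP data cannot fall below the OP fit (nesting)", {
  set.seed(55)
  n <- 1500
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  ystar <- 0.7 * d$x3 + rnorm(n)
  d$y <- as.integer(findInterval(ystar, c(0.5, 1.2, 2.0)))
  obs_op <- build_design(d, equation_spec("y", xy = "x3"), "OP")
  obs_dz <- suppressWarnings(
    build_design(d, equation_spec("y", xr = "x1", xm = "x2", xy = "x3"),
                 "DZIOP"))
  f_op <- dziop_fit(obs_op, "OP", control = dziop_control(se = "none"))
  f_dz <- dziop_fit(obs_dz, "DZIOP",
                    control = dziop_control(se = "none",
                                            optimizer = "nlminb"))
  expect_gte(f_dz$loglik, f_op$loglik - 1e-6)
})

test_that("LR independence test follows the chi-square recipe", {
  f1 <- structure(list(variant = "DZIOPC", n_obs = 100, loglik = -100,
                       skel = list(nrho = 3L),
                       params = list(beta_r = 1:2, beta_m = 1:2,
                                     beta_y = 1:2)),
                  class = "dziop")
  f0 <- structure(list(variant = "DZIOP", n_obs = 100, loglik = -102,
                       skel = list(nrho = 0L),
                       params = list(beta_r = 1:2, beta_m = 1:2,
                                     beta_y = 1:2)),
                  class = "dziop")
  lt <- lr_independence_test(f1, f0)
  expect_equal(lt$statistic, 4)
  expect_equal(lt$df, 3)
  expect_equal(lt$p_value, pchisq(4, 3, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(lt$p_value, 4), 0.2615)
  # equal log-likelihoods: statistic clipped at zero, p = 1
  f0$loglik <- -100
  lt0 <- lr_independence_test(f1, f0)
  expect_equal(lt0$statistic, 0)
  expect_equal(lt0$p_value, 1)
  # simulated log-likelihood microscopically below: still clipped
  f0$loglik <- -99.9999
  expect_equal(lr_independence_test(f1, f0)$statistic, 0)
  # mismatched pairs rejected
  f0$variant <- "ZIOP"
  expect_error(lr_independence_test(f1, f0), "counterpart")
})

test_that("non-convergence is reported, not thrown", {
  sh <- small_dziop_fit()
  obs <- sh$fit$obs
  f <- dziop_fit(obs, "DZIOP", start = sh$cfg$params,
                 control = dziop_control(se = "none", max_iter = 2L))
  expect_s3_class(f, "dziop")
  expect_false(f$converged)
  expect_true(is.finite(f$loglik))
})
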