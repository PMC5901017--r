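test_that("covariate generation is reproducible and hits prevalences", {
  cfg <- cannabis_preset("full", n = 50000, seed = 4)
  d1 <- gen_covariates(cfg)
  d2 <- gen_covariates(cfg)
  expect_identical(d1, d2)
  # binary prevalence within 3 binomial standard errors
  p <- 0.466
  expect_lt(abs(mean(d1$male) - p), 3 * sqrt(p * (1 - p) / nrow(d1)))
  # squared column is centred
  expect_lt(abs(mean(d1$stagesq)), 1e-10)
  # degenerate prevalence
  cfg0 <- dgp_config(100, 1,
                     covariates = list(list(name = "b", kind = "binary",
                                            p = 0)),
                     spec = cannabis_preset("minimal")$spec,
                     params = cannabis_preset("minimal")$params)
  expect_true(all(gen_covariates(cfg0)$b == 0))
  expect_error(dgp_config(10, 1,
                          covariates = list(list(name = "b",
                                                 kind = "binary", p = 1.2)),
                          spec = cfg$spec, params = cfg$params),
               "prevalence")
})

test_that("observability rule y = r * m * ytilde holds exactly", {
  cfg <- cannabis_preset("condensed", n = 20000, seed = 12)
  sim <- simulate_dziop(cfg)
  lat <- sim$latent
  expect_identical(lat$y, lat$r * lat$m * lat$y_tilde)
  expect_identical(lat$r, as.integer(lat$r_star > 0))
  expect_identical(lat$m, as.integer(lat$m_star > 0))
  # y > 0 implies participation and truthful reporting
  pos <- lat$y > 0
  expect_true(all(lat$r[pos] == 1L))
  expect_true(all(lat$m[pos] == 1L))
})

test_that("a degenerate misreporting hurdle removes misreporters", {
  cfg <- cannabis_preset("minimal", n = 20000, seed = 9)
  pa <- cfg$params
  pa$beta_m[1] <- 10
  cfg2 <- dgp_config(cfg$n, cfg$seed, cfg$covariates, cfg$spec, pa)
  sim <- simulate_dziop(cfg2)
  expect_equal(sum(sim$latent$m == 0), 0)
  # observed zeros are then nonparticipants plus truthful zero consumers
  lat <- sim$latent
  expect_equal(sum(lat$y == 0),
               sum(lat$r == 0) + sum(lat$r == 1 & lat$y_tilde == 0))
})

test_that("empirical frequencies match analytic probabilities", {
  for (variant in c("DZIOP", "DZIOPC")) {
    cfg <- cannabis_preset("condensed", n = 40000, seed = 31,
                           variant = variant)
    sim <- simulate_dziop(cfg)
    obs <- build_design(sim$data, cfg$spec, variant)
    p <- category_probs(cfg$params, obs, n_draws = 200, seed = 2)
    expected <- colMeans(p)
    emp <- tabulate(sim$data$y + 1L, nbins = obs$J + 1L) / obs$n
    se3 <- 3 * sqrt(expected * (1 - expected) / obs$n)
    expect_true(all(abs(emp - expected) < se3 + 2e-3),
                label = paste(variant, "category frequencies"))
    # zero components against realised latent states
    cc <- colMeans(zero_components(cfg$params, obs, n_draws = 200, seed = 2))
    lat <- sim$latent
    realised <- c(mean(lat$r == 0), mean(lat$r == 1 & lat$m == 0),
                  mean(lat$r == 1 & lat$m == 1 & lat$y_tilde == 0))
    se3c <- 3 * sqrt(pmax(realised * (1 - realised), 1e-4) / obs$n)
    expect_true(all(abs(cc - realised) < se3c + 2e-3),
                label = paste(variant, "zero components"))
  }
})

test_that("truth_shares sums to one and handles edge cases", {
  cfg <- cannabis_preset("minimal", n = 5000, seed = 2)
  sim <- simulate_dziop(cfg)
  ts <- truth_shares(sim$latent)
  expect_equal(sum(ts), 1, tolerance = 1e-12)
  expect_true(all(ts >= 0))
  # nonparticipation dominates under survey-like coefficients
  expect_gt(ts[["nonparticipation"]], 0.5)
  # all nonparticipants
  lat <- data.frame(r = 0L, m = 1L, y_tilde = 2L, y = 0L)
  expect_equal(unname(truth_shares(lat)), c(1, 0, 0))
  lat2 <- data.frame(r = 1L, m = 1L, y_tilde = 2L, y = 2L)
  expect_error(truth_shares(lat2), "no observed zeros")
})

test_that("presets are valid and produce survey-like zero inflation", {
  for (design in c("full", "condensed", "minimal")) {
    for (variant in c("DZIOP", "DZIOPC")) {
      cfg <- cannabis_preset(design, n = 30000, seed = 6, variant = variant)
      expect_s3_class(cfg$params, "dziop_params")
      expect_equal(cfg$params$mu, c(0.819, 1.568))
      expect_true(all(diff(c(0, cfg$params$mu)) > 0))
      ev <- eigen(dziop:::corr3(cfg$params$rho), only.values = TRUE)$values
      expect_gt(min(ev), 0)
      sim <- simulate_dziop(cfg)
      zs <- mean(sim$data$y == 0)
      expect_gt(zs, 0.80)
      expect_lt(zs, 0.95)
    }
  }
})

test_that("correlated errors actually correlate the latent shocks", {
  cfg <- cannabis_preset("minimal", n = 60000, seed = 13, variant = "DZIOPC")
  sim <- simulate_dziop(cfg)
  lat <- sim$latent
  # residual correlation of the r* and m* shocks
  obs <- build_design(sim$data, cfg$spec, "DZIOPC")
  er <- lat$r_star - drop(obs$Xr %*% cfg$params$beta_r)
  em <- lat$m_star - drop(obs$Xm %*% cfg$params$beta_m)
  ey <- lat$y_star - drop(obs$Xy %*% cfg$params$beta_y)
  expect_lt(abs(cor(er, em) - (-0.591)), 0.02)
  expect_lt(abs(cor(er, ey) - 0.038), 0.02)
  expect_lt(abs(cor(em, ey) - 0.280), 0.02)
})
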