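test_that("partial effects decompose additively in both modes", {
  sh <- small_dziop_fit()
  fit <- sh$fit
  for (mode in c("at_means", "average")) {
    pe <- partial_effects(fit, mode = mode, se = FALSE)
    tab <- pe$table
    for (term in unique(tab$term)) {
      tt <- tab[tab$term == term, ]
      comp <- tt$estimate[match(c("nonparticipation", "misreporting",
                                  "zero_consumption"), tt$target)]
      overall <- tt$estimate[tt$target == "zero_total"]
      expect_equal(sum(comp), overall, tolerance = 1e-8,
                   label = paste(mode, term, "component sum"))
      expect_equal(overall, tt$estimate[tt$target == "cat_0"],
                   tolerance = 1e-8)
      cats <- tt$estimate[grepl("^cat_", tt$target)]
      expect_equal(sum(cats), 0, tolerance = 1e-8,
                   label = paste(mode, term, "categories sum"))
    }
  }
})

test_that("a covariate in no equation has exactly zero effect", {
  sh <- small_dziop_fit()
  fit <- sh$fit
  dat <- fit$data
  dat$unused <- rnorm(nrow(dat))
  pe <- partial_effects(fit, data = dat, covariates = c("male", "unused"),
                        se = FALSE)
  un <- pe$table[pe$table$term == "unused", ]
  expect_true(all(un$estimate == 0))
  expect_true(all(un$se == 0 | is.na(un$se)))
})

test_that("continuous effects match a brute-force probability difference", {
  sh <- small_dziop_fit()
  fit <- sh$fit
  pe <- partial_effects(fit, mode = "at_means", covariates = "stage",
                        se = FALSE)
  got <- pe$table$estimate[pe$table$target == "zero_total"]
  # oracle: rebuild the at-means row and difference P(y=0) directly through
  # category_probs with the same two-point stencil
  dat <- fit$data
  mrow <- as.data.frame(lapply(dat[, names(dat) != "y", drop = FALSE], mean))
  h <- 1e-6
  p_at <- function(row) {
    obs <- dziop:::design_only(row, fit$obs$spec, fit$J)
    category_probs(fit$params, obs)[1, 1]
  }
  up <- mrow; up$stage <- up$stage + h
  dn <- mrow; dn$stage <- dn$stage - h
  oracle <- (p_at(up) - p_at(dn)) / (2 * h)
  expect_equal(got, unname(oracle), tolerance = 1e-6)
})

test_that("binary covariates support both discrete and derivative handling", {
  sh <- small_dziop_fit()
  fit <- sh$fit
  pd <- partial_effects(fit, covariates = "male", dummies = "discrete",
                        se = FALSE)
  pv <- partial_effects(fit, covariates = "male", dummies = "derivative",
                        se = FALSE)
  # both satisfy additivity but differ numerically
  e1 <- pd$table$estimate[pd$table$target == "zero_total"]
  e2 <- pv$table$estimate[pv$table$target == "zero_total"]
  expect_false(isTRUE(all.equal(e1, e2)))
  for (pe in list(pd, pv)) {
    tt <- pe$table
    comp <- tt$estimate[match(c("nonparticipation", "misreporting",
                                "zero_consumption"), tt$target)]
    expect_equal(sum(comp), tt$estimate[tt$target == "zero_total"],
                 tolerance = 1e-8)
  }
})

test_that("delta-method margins standard errors are finite and positive", {
  sh <- small_dziop_fit()
  fit <- sh$fit
  pe <- partial_effects(fit, covariates = c("male", "stage"), se = TRUE)
  expect_true(all(is.finite(pe$table$se)))
  expect_true(all(pe$table$se[pe$table$estimate != 0] > 0))
})

test_that("posterior shares normalise the zero components", {
  m <- list()
  d <- data.frame(y = c(0L, 0L, 1L, 2L, 3L), x = 0)
  sp <- equation_spec("y", xr = "x", xm = "x", xy = "x")
  obs <- suppressWarnings(build_design(d, sp))
  pa <- parameter_set("DZIOP", beta_r = c(0, 0), beta_m = c(0, 0),
                      beta_y = c(0, 0), mu = c(0.8, 1.6))
  fit <- fit_stub(pa, obs)
  po <- posterior_zero_shares(fit, se = FALSE)
  # hand value: (0.5, 0.25, 0.125) / 0.875
  expect_equal(unname(po$average), c(0.5, 0.25, 0.125) / 0.875,
               tolerance = 1e-10)
  expect_equal(sum(po$average), 1, tolerance = 1e-10)
  expect_equal(rowSums(po$shares), rep(1, 2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(po$n_zero, 2L)
})

test_that("posterior shares hit the boundary cases", {
  # participation probability ~ 0: the zero must come from nonparticipation
  d <- data.frame(y = 0L, x = 0)
  sp <- equation_spec("y", xr = "x", xm = "x", xy = "x")
  obs <- suppressWarnings(build_design(rbind(d, data.frame(y = 1L, x = 0),
                                             data.frame(y = 2L, x = 0)), sp))
  pa <- parameter_set("DZIOP", beta_r = c(-15, 0), beta_m = c(0, 0),
                      beta_y = c(0, 0), mu = 0.8)
  fit <- fit_stub(pa, obs)
  po <- posterior_zero_shares(fit, se = FALSE)
  expect_equal(unname(po$average), c(1, 0, 0), tolerance = 1e-10)
  # no zeros at all -> error
  obs_nz <- dziop:::subset_obs(obs, obs$y > 0)
  expect_error(posterior_zero_shares(fit, obs_nz), "no observed zeros")
})

test_that("prior summary averages components over all rows", {
  sh <- small_dziop_fit()
  fit <- sh$fit
  pr <- prior_zero_summary(fit, se = FALSE)
  cc <- zero_components(fit$params, fit$obs)
  expect_equal(unname(pr$average), unname(colMeans(cc)), tolerance = 1e-12)
  expect_equal(pr$total, mean(category_probs(fit$params, fit$obs)[, 1]),
               tolerance = 1e-10)
  zt <- zero_summary_table(fit, se = FALSE)
  expect_equal(zt["marginal", "full"], pr$total, tolerance = 1e-12)
  expect_equal(zt["posterior", "full"], 1)
})

test_that("averaged components match realised latent frequencies", {
  sh <- small_dziop_fit(n = 8000, seed = 21)
  fit <- sh$fit
  lat <- sh$sim$latent
  pr <- prior_zero_summary(fit, se = FALSE)
  n <- nrow(lat)
  truth <- c(mean(lat$r == 0), mean(lat$r == 1 & lat$m == 0),
             mean(lat$r == 1 & lat$m == 1 & lat$y_tilde == 0))
  se3 <- 3 * sqrt(pmax(truth * (1 - truth), 1e-4) / n)
  expect_true(all(abs(pr$average - truth) < se3 + 0.01))
})

test_that("delta-method posterior errors agree with a bootstrap", {
  # the first-order delta method needs the asymptotic regime: this runs on
  # the well-identified minimal design at a size where the parameter
  # spread is small enough for the linearisation (at n = 2000 the share
  # functionals are visibly curved over the bootstrap spread and a
  # first-order method genuinely disagrees; see the methods vignette)
  sh <- small_dziop_fit(n = 8000, seed = 45, design = "minimal")
  fit <- sh$fit
  po <- posterior_zero_shares(fit)
  set.seed(99)
  B <- 200
  boot <- matrix(0, B, 3)
  for (b in seq_len(B)) {
    idx <- sample.int(fit$n_obs, replace = TRUE)
    obs_b <- dziop:::subset_obs(fit$obs, idx)
    fb <- dziop_fit(obs_b, "DZIOP", start = fit$params,
                    control = dziop_control(se = "none",
                                            optimizer = "nlminb",
                                            tol_loglik = 1e-7,
                                            max_iter = 150))
    pb <- posterior_zero_shares(fb, se = FALSE)
    boot[b, ] <- pb$average
  }
  boot_se <- apply(boot, 2, sd)
  expect_true(all(abs(po$se / boot_se - 1) < 0.20))
})
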