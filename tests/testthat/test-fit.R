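test_that("noise-free data are recovered to high accuracy", {
  tr <- dr_params("exponential", a = 0.25, ced = 10, c = 15, d = 1,
                  log_sd = 1e-12)
  ds <- generate_study(study_design(c(0, 1, 10, 100), 5, "DO"), tr, seed = 1)
  fit <- fit_dr_model(ds, "exponential", 0.5,
                      covariate_config(FALSE, FALSE, FALSE),
                      n_starts = 20, seed = 1)
  expect_equal(unname(fit$params$a), 0.25, tolerance = 1e-3)
  expect_equal(unname(fit$params$ced), 10, tolerance = 1e-3)
  expect_equal(fit$params$c, 15, tolerance = 1e-3)
  expect_equal(fit$params$d, 1, tolerance = 1e-3)
})

test_that("the MLE beats a coarse 4-D grid search on a 6-group fixture", {
  ds <- tiny_study(seed = 11, n = 8)
  fit <- fit_dr_model(ds, "exponential", 0.5,
                      covariate_config(FALSE, FALSE, FALSE),
                      n_starts = 20, seed = 1)
  # independent brute-force oracle: grid over (a, ced, c, d) with the
  # residual SD profiled in closed form from the log-scale residuals
  sm <- as_summary(ds)$data
  n <- sm$n
  mlog <- log(sm$mean / sqrt(1 + (sm$sd / sm$mean)^2))
  ss <- n * log(1 + (sm$sd / sm$mean)^2)
  N <- sum(n)
  grid_ll <- function(a, ced, c, d) {
    p <- dr_params("exponential", a = a, ced = ced, c = c, d = d,
                   log_sd = 0.3)
    mu <- dr_predict(p, sm$dose, 0.5)
    s2 <- sum(ss + n * (mlog - log(mu))^2) / N
    -N / 2 * (log(2 * pi * s2) + 1)
  }
  best_grid <- -Inf
  for (a in exp(seq(log(0.1), log(1), length.out = 10)))
    for (ced in exp(seq(log(1), log(100), length.out = 12)))
      for (c in 1.5 + exp(seq(log(0.5), log(50), length.out = 10)))
        for (d in seq(0.25, 4, length.out = 8))
          best_grid <- max(best_grid, grid_ll(a, ced, c, d))
  expect_true(best_grid <= fit$log_lik + 1e-6)
})

test_that("estimated CED lies inside the fit's own 90% profile interval", {
  ds <- two_strain_dataset(seed = 1)
  fit <- fit_dr_model(ds, "exponential", 0.5, covariate_config(TRUE, TRUE),
                      n_starts = 8, seed = 1)
  ci <- profile_ci(fit)
  expect_true(all(ci$bmcl <= ci$ced & ci$ced <= ci$bmcu))
  # simulated truth (CED 10 for DO, 8 for B6C3F1) inside the intervals
  expect_true(ci$bmcl[ci$covariate == "DO"] <= 10 &&
                10 <= ci$bmcu[ci$covariate == "DO"])
})

test_that("AIC bookkeeping is consistent and nesting cannot raise the likelihood", {
  ds <- two_strain_dataset(seed = 4)
  cfgs <- list(covariate_config(FALSE, FALSE, FALSE),
               covariate_config(TRUE, FALSE, FALSE),
               covariate_config(TRUE, TRUE, FALSE),
               covariate_config(TRUE, TRUE, TRUE))
  fits <- lapply(cfgs, function(cc) fit_dr_model(ds, "exponential", 0.5, cc,
                                                 n_starts = 8, seed = 1))
  ll <- vapply(fits, `[[`, numeric(1), "log_lik")
  k <- vapply(fits, `[[`, numeric(1), "n_free_params")
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  expect_identical(aic, 2 * k - 2 * ll)     # recomputed AIC matches exactly
  expect_true(all(diff(ll) >= -1e-6))       # more free params, never worse
  # pinning c near its lower limit can never beat the free model
  free <- fits[[3]]
  pinned <- fit_dr_model(ds, "exponential", 0.5, covariate_config(TRUE, TRUE),
                         n_starts = 8, seed = 1, fixed = list(c = 1.5 + 1e-3))
  expect_true(pinned$log_lik <= free$log_lik + 1e-6)
})

test_that("fits are dose-scale equivariant and response-scale invariant", {
  ds <- tiny_study(seed = 21, n = 10)
  fit <- fit_dr_model(ds, "exponential", 0.5,
                      covariate_config(FALSE, FALSE, FALSE),
                      n_starts = 10, seed = 3)
  k <- 4.2
  d2 <- ds$data
  d2$dose <- d2$dose * k
  fit_k <- fit_dr_model(dr_dataset(d2), "exponential", 0.5,
                        covariate_config(FALSE, FALSE, FALSE),
                        n_starts = 10, seed = 3)
  expect_equal(unname(fit_k$params$ced), k * unname(fit$params$ced),
               tolerance = 1e-3)
  ci <- profile_ci(fit)
  ci_k <- profile_ci(fit_k)
  expect_equal(ci_k$bmcl, k * ci$bmcl, tolerance = 2e-3)
  expect_equal(ci_k$bmcu, k * ci$bmcu, tolerance = 2e-3)
  d3 <- ds$data
  d3$response <- d3$response * k
  fit_r <- fit_dr_model(dr_dataset(d3), "exponential", 0.5,
                        covariate_config(FALSE, FALSE, FALSE),
                        n_starts = 10, seed = 3)
  expect_equal(unname(fit_r$params$a), k * unname(fit$params$a),
               tolerance = 1e-3)
  expect_equal(unname(fit_r$params$ced), unname(fit$params$ced),
               tolerance = 1e-3)
})

test_that("identical inputs and seed give bit-identical fits", {
  ds <- tiny_study(seed = 8, n = 6)
  f1 <- fit_dr_model(ds, "hill", 0.5, covariate_config(FALSE, FALSE, FALSE),
                     n_starts = 6, seed = 5)
  f2 <- fit_dr_model(ds, "hill", 0.5, covariate_config(FALSE, FALSE, FALSE),
                     n_starts = 6, seed = 5)
  expect_identical(serialize(f1, NULL), serialize(f2, NULL))
})

test_that("design and convergence guards fire", {
  too_few <- dr_dataset(data.frame(dose = c(0, 0, 10, 10),
                                   response = c(0.2, 0.3, 0.4, 0.5)))
  expect_error(fit_dr_model(too_few, "exponential", 0.5), "3 distinct doses")
})

test_that("structure selection recovers the generating covariate structure", {
  # identical truth across strains -> the all-shared structure should win
  tr <- dr_params("exponential", a = 0.25, ced = 10, c = 15, d = 1,
                  log_sd = 0.4)
  des1 <- study_design(c(0, 1, 10, 100), 25, "S1")
  des2 <- study_design(c(0, 1, 10, 100), 25, "S2")
  n_shared <- 0
  for (r in 1:50) {
    ds <- dr_dataset(rbind(generate_study(des1, tr, seed = 1000 + r)$data,
                           generate_study(des2, tr, seed = 2000 + r)$data))
    sel <- select_covariate_structure(ds, "exponential", 0.5, n_starts = 4,
                                      seed = 1)
    cfg <- sel$config
    if (!cfg$a_split && !cfg$ced_split && !cfg$log_sd_split)
      n_shared <- n_shared + 1
  }
  expect_gte(n_shared, 40)   # >= 80% of 50 replicates

  # 3-fold CED difference at n = 75/group -> a CED-split structure
  tr_a <- dr_params("exponential", a = 0.25, ced = 5, c = 15, d = 1,
                    log_sd = 0.4)
  tr_b <- dr_params("exponential", a = 0.25, ced = 15, c = 15, d = 1,
                    log_sd = 0.4)
  des75 <- function(lab) study_design(c(0, 1, 10, 100), 75, lab)
  n_split <- 0
  for (r in 1:50) {
    ds <- dr_dataset(rbind(
      generate_study(des75("S1"), tr_a, seed = 3000 + r)$data,
      generate_study(des75("S2"), tr_b, seed = 4000 + r)$data))
    sel <- select_covariate_structure(ds, "exponential", 0.5, n_starts = 4,
                                      seed = 1)
    if (sel$config$ced_split) n_split <- n_split + 1
  }
  expect_gte(n_split, 45)    # >= 90% of 50 replicates
})

test_that("a single covariate level falls back to a plain shared fit", {
  ds <- tiny_study(seed = 2, n = 8)
  sel <- select_covariate_structure(ds, "exponential", 0.5, n_starts = 6,
                                    seed = 1)
  expect_false(sel$config$a_split || sel$config$ced_split ||
                 sel$config$log_sd_split)
  expect_identical(nrow(sel$covariate_selection), 1L)
})
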