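test_that("parameter validation rejects out-of-domain values", {
  expect_error(dr_params("exponential", a = -1, ced = 10, c = 5, d = 1), "'a'")
  expect_error(dr_params("exponential", a = 1, ced = 0, c = 5, d = 1), "ced")
  expect_error(dr_params("exponential", a = 1, ced = 10, c = 1, d = 1), "'c'")
  expect_error(dr_params("exponential", a = 1, ced = 10, c = 5, d = 0), "'d'")
  expect_error(dr_params("exponential", a = 1, ced = 10, c = 5, d = 1,
                         log_sd = 0), "log_sd")
  p <- dr_params("hill", a = 1, ced = 10, c = 1.4, d = 1)
  expect_error(dr_predict(p, 1, ces = 0.5), "CED undefined")
  expect_error(b_from_ced(p, 0.5), "CED undefined")
})

test_that("predict honours the CED parameterisation identities", {
  for (fam in c("exponential", "hill")) {
    p <- dr_params(fam, a = 2, ced = 10, c = 5, d = 1.3, log_sd = 0.3)
    expect_equal(dr_predict(p, 0, 0.5), 2)                   # y(0) = a
    expect_equal(dr_predict(p, 10, 0.5), 2 * 1.5)            # y(CED) = a(1+ces)
  }
  # hand-derived scalar evaluation: b = -log(3.5/4)/10, then the closed form
  p <- dr_params("exponential", a = 2, ced = 10, c = 5, d = 1)
  b <- -log(3.5 / 4) / 10
  expect_equal(b_from_ced(p, 0.5), b, tolerance = 1e-12)
  expect_equal(dr_predict(p, 20, 0.5), 2 * (5 - 4 * exp(-b * 20)),
               tolerance = 1e-12)
  expect_equal(dr_predict(p, 20, 0.5), 3.875, tolerance = 1e-9)
  # Hill with c = 2, ces = 0.5: CED is the half-maximum dose, so b = ced
  ph <- dr_params("hill", a = 1, ced = 7, c = 2, d = 2.2)
  expect_equal(b_from_ced(ph, 0.5), 7, tolerance = 1e-12)
  # independently evaluated: b = -log(0.875)/10 for c=5, ces=0.5, ced=10, d=1
  expect_equal(b_from_ced(p, 0.5), 0.0133531393, tolerance = 1e-7)
})

test_that("reparameterisation round-trip holds for random parameter draws", {
  withr::with_seed(42, {
    for (i in 1:100) {
      p <- random_params()
      expect_equal(dr_predict(p, p$ced, 0.5), p$a * 1.5, tolerance = 1e-12)
    }
  })
})

test_that("predict is nondecreasing in dose and approaches the plateau a*c", {
  withr::with_seed(7, {
    for (i in 1:50) {
      p <- random_params()
      doses <- sort(stats::runif(20, 0, 50 * p$ced))
      y <- dr_predict(p, doses, 0.5)
      expect_true(all(diff(y) >= -1e-12))
      expect_true(all(y <= p$a * p$c + 1e-9))
    }
  })
  # plateau: the exponential family converges exponentially fast, the Hill
  # family hyperbolically, so the Hill check needs a much larger dose
  pe <- dr_params("exponential", a = 2, ced = 10, c = 5, d = 1)
  expect_equal(dr_predict(pe, 1000 * 10, 0.5), 2 * 5, tolerance = 1e-6)
  ph <- dr_params("hill", a = 2, ced = 10, c = 5, d = 1)
  expect_equal(dr_predict(ph, 1e7 * 10, 0.5), 2 * 5, tolerance = 1e-6)
})

test_that("predict is dose-scale equivariant and response-scale linear", {
  p <- dr_params("hill", a = 0.4, ced = 8, c = 12, d = 1.7)
  doses <- c(0, 1, 4, 9, 30)
  k <- 3.7
  pk <- dr_params("hill", a = 0.4, ced = 8 * k, c = 12, d = 1.7)
  expect_equal(dr_predict(pk, doses * k, 0.5), dr_predict(p, doses, 0.5),
               tolerance = 1e-12)
  pa <- dr_params("hill", a = 0.4 * k, ced = 8, c = 12, d = 1.7)
  expect_equal(dr_predict(pa, doses, 0.5), k * dr_predict(p, doses, 0.5),
               tolerance = 1e-12)
})

test_that("log-likelihood matches per-observation summation and is exchangeable", {
  p <- dr_params("exponential", a = 0.3, ced = 12, c = 8, d = 1, log_sd = 0.4)
  # 2 groups x 3 subjects, fixed params: brute-force term-by-term oracle
  df <- data.frame(dose = rep(c(0, 10), each = 3),
                   response = c(0.28, 0.35, 0.22, 0.5, 0.41, 0.44))
  ds <- dr_dataset(df)
  mu <- dr_predict(p, df$dose, 0.5)
  oracle <- sum(stats::dnorm(log(df$response), log(mu), p$log_sd, log = TRUE))
  expect_equal(dr_loglik(p, 0.5, ds), oracle, tolerance = 1e-10)
  # permuting rows leaves the likelihood unchanged
  ds2 <- dr_dataset(df[c(4, 1, 6, 3, 2, 5), ])
  expect_equal(dr_loglik(p, 0.5, ds2), oracle, tolerance = 1e-10)
})

test_that("data equal to the model medians give the zero-residual likelihood", {
  p <- dr_params("exponential", a = 0.3, ced = 12, c = 8, d = 1, log_sd = 0.25)
  doses <- c(0, 5, 20, 80)
  df <- data.frame(dose = rep(doses, each = 2),
                   response = rep(dr_predict(p, doses, 0.5), each = 2))
  n <- nrow(df)
  expect_equal(dr_loglik(p, 0.5, dr_dataset(df)),
               -(n / 2) * log(2 * pi * p$log_sd^2), tolerance = 1e-10)
})

test_that("summary-mode transform inverts the lognormal moments", {
  # arithmetic moments of a lognormal: m = exp(mu + s2/2), sd^2 = m^2(e^s2 - 1)
  mu <- -1.2; s2 <- 0.16; n <- 9
  m <- exp(mu + s2 / 2)
  s <- sqrt(m^2 * (exp(s2) - 1))
  ds <- dr_dataset(data.frame(dose = c(0, 5, 20), n = n, mean = m, sd = s))
  st <- bmdrisk:::suff_stats(ds)
  expect_equal(st$mlog, rep(mu, 3), tolerance = 1e-12)
  expect_equal(st$ss, rep(n * s2, 3), tolerance = 1e-12)
})

test_that("non-positive responses are rejected unless an offset is supplied", {
  df <- data.frame(dose = c(0, 0, 5, 5, 20, 20), response = c(0, 0.3, 0.4,
                                                              0.5, 0.8, 1))
  ds <- dr_dataset(df)
  p <- tiny_truth()
  expect_error(dr_loglik(p, 0.5, ds), "non-positive response")
  expect_true(is.finite(dr_loglik(p, 0.5, ds, offset = 0.05)))
})
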