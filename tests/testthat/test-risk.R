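test_that("half-up significant-figure rounding matches the reporting rules", {
  expect_identical(signif_half_up(3.55), 3.6)    # exact half rounds up
  expect_identical(signif_half_up(14.2 / 4), 3.6) # binary half just short
  expect_identical(signif_half_up(3.549), 3.5)
  expect_identical(signif_half_up(7.1355), 7.1)
  expect_identical(signif_half_up(0.16246), 0.16)
  expect_identical(signif_half_up(31.5555), 32)
  expect_identical(signif_half_up(0), 0)
  expect_identical(signif_half_up(-3.55), -3.6)
})

test_that("gas conversions reproduce the printed values and round-trip", {
  expect_equal(signif_half_up(ppm_to_mgm3(0.05)), 0.16)
  expect_equal(signif_half_up(ugm3_to_ppb(5)), 1.5)
  expect_identical(ppm_to_mgm3(0), 0)
  # full-precision round trip; rounding is a reporting-layer decision only
  x <- c(0.013, 0.05, 7.4, 120)
  expect_equal(mgm3_to_ppm(ppm_to_mgm3(x)), x, tolerance = 1e-14)
  expect_equal(ppb_to_ugm3(ugm3_to_ppb(x)), x, tolerance = 1e-14)
  expect_error(ppm_to_mgm3(-1), ">= 0")
})

test_that("human-equivalent PoD reproduces the worker and general chains", {
  pod <- pod_range(9.6, 14.2, basis = "BMCL50/BMCU50")
  w <- human_equivalent_pod(pod, worker_adjustment())
  expect_identical(c(w$lower, w$upper), c(4.8, 7.1))
  g <- human_equivalent_pod(pod, general_population_adjustment())
  expect_identical(c(g$lower, g$upper), c(2.4, 3.6))
  # identity adjustment leaves the range unchanged
  id <- exposure_adjustment(6, 6, 2, 2)
  u <- human_equivalent_pod(pod, id)
  expect_identical(c(u$lower, u$upper), c(9.6, 14))  # 14.2 reports as 14
  u2 <- human_equivalent_pod(pod, id, rounded = FALSE)
  expect_identical(c(u2$lower, u2$upper), c(9.6, 14.2))
})

test_that("assessment factors compose multiplicatively", {
  expect_identical(compose_afs(benzene_worker_afs()), 225)
  expect_identical(compose_afs(benzene_general_afs()), 450)
  expect_warning(one <- compose_afs(assessment_factors(numeric(0))), "empty")
  expect_identical(one, 1)
  expect_warning(assessment_factors(0.5), "below 1")
  expect_error(assessment_factors(c(2, -1)), "> 0")
})

test_that("acceptable ranges reproduce the printed worker/general values", {
  expect_identical(acceptable_range(pod_range(4.8, 7.1), 225)[c("lower", "upper")],
                   list(lower = 21, upper = 32))
  expect_identical(acceptable_range(pod_range(2.4, 3.6), 450)[c("lower", "upper")],
                   list(lower = 5.3, upper = 8))
  # AF = 1: plain ppm -> ppb conversion
  expect_identical(acceptable_range(pod_range(2.4, 3.6), 1)[c("lower", "upper")],
                   list(lower = 2400, upper = 3600))
})

test_that("acceptable bounds are monotone in PoD and composite AF", {
  base <- acceptable_range(pod_range(4.8, 7.1), 225)
  bigger_af <- acceptable_range(pod_range(4.8, 7.1), 450)
  expect_true(bigger_af$upper <= base$upper && bigger_af$lower <= base$lower)
  bigger_pod <- acceptable_range(pod_range(5.8, 8.1), 225)
  expect_true(bigger_pod$lower >= base$lower && bigger_pod$upper >= base$upper)
})

test_that("margin of exposure behaves as a ratio", {
  expect_identical(margin_of_exposure(5, 5), 1)
  expect_equal(margin_of_exposure(4.8, 0.05), 96)
  expect_equal(margin_of_exposure(4.8, 0.1), 48)  # doubling halves the MOE
  expect_error(margin_of_exposure(4.8, 0), "exposure")
})

test_that("risk verdicts follow the range-comparison rule", {
  expect_identical(characterize_risk(c(21, 32), c(50, 100)), "above")
  expect_identical(characterize_risk(c(5.3, 8), c(1.5, 1.5)), "below")
  expect_identical(characterize_risk(c(21, 32), c(32, 40)), "within")
  expect_identical(characterize_risk(list(lower = 21, upper = 32),
                                     list(lower = 10, upper = 22)), "within")
})

test_that("aggregate exposure sums sources order-independently", {
  expect_identical(aggregate_exposure(c(road = 1.2))$total, 1.2)
  expect_identical(aggregate_exposure(c(a = 0, b = 0, c = 0))$total, 0)
  ab <- aggregate_exposure(c(a = 1.1, b = 2.3))
  ba <- aggregate_exposure(c(b = 2.3, a = 1.1))
  expect_identical(ab$total, ba$total)
  expect_error(aggregate_exposure(c(a = -1)), ">= 0")
})
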