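#' Inhalation study design
#'
#' Describes a dose-group design for a simulated micronucleus study:
#' exposure concentrations, group size and the exposure-regimen metadata
#' (hours/day, days/week, weeks) carried as annotation for the
#' human-equivalent conversion downstream.
#'
#' @param doses exposure concentrations (ppm), at least 3 distinct values.
#' @param n_per_group animals per dose group, `>= 1`.
#' @param covariate_label strain / study label attached to every record.
#' @param hours_per_day,days_per_week,weeks exposure regimen annotation.
#' @return an object of class `study_design`.
#' @export
study_design <- function(doses, n_per_group, covariate_label = "strain",
                         hours_per_day = 6, days_per_week = 5, weeks = 4) {
  if (length(unique(doses)) < 3)
    stop("a design needs at least 3 distinct doses", call. = FALSE)
  if (any(doses < 0)) stop("doses must be >= 0", call. = FALSE)
  if (n_per_group < 1) stop("n_per_group must be >= 1", call. = FALSE)
  structure(list(doses = sort(doses), n_per_group = as.integer(n_per_group),
                 covariate_label = covariate_label,
                 hours_per_day = hours_per_day,
                 days_per_week = days_per_week, weeks = weeks),
            class = "study_design")
}

#' Simulate a dose-response study under the lognormal model
#'
#' Draws per-animal responses as `dr_predict(truth, dose) * exp(e)` with
#' `e ~ Normal(0, log_sd^2)` — exactly the error model the fitting layer
#' assumes, so parameter-recovery experiments are well-posed. Deterministic
#' for a given seed. The true parameters, CES, design and seed are attached
#' as attributes for test harnesses and written to the JSON sidecar by
#' [write_dr_dataset()].
#'
#' @param design a [study_design()].
#' @param truth a [dr_params] ground-truth parameter set.
#' @param seed integer seed.
#' @param ces critical effect size under which `truth$ced` is interpreted.
#' @return an individual-mode [dr_dataset] (use [as_summary()] for the
#'   group-summary view).
#' @export
generate_study <- function(design, truth, seed, ces = 0.5) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "dr_params"))
  mu <- dr_predict(truth, design$doses, ces)
  df <- with_local_seed(seed, {
    do.call(rbind, lapply(seq_along(design$doses), function(i) {
      data.frame(dose = design$doses[i],
                 covariate = design$covariate_label,
                 response = mu[i] * exp(stats::rnorm(design$n_per_group,
                                                     0, truth$log_sd)))
    }))
  })
  ds <- dr_dataset(df)
  attr(ds, "truth") <- c(unclass(truth), list(ces = ces))
  attr(ds, "design") <- unclass(design)
  attr(ds, "seed") <- seed
  ds
}

#' Two-study benzene-like fixture (synthetic)
#'
#' Generates a pair of synthetic micronucleated-reticulocyte studies with
#' the structure of the benzene inhalation literature: a Diversity Outbred
#' (DO)-like study (0/1/10/100 ppm, 75 animals per group, 6 h/day,
#' 5 days/week, 4 weeks) and a B6C3F1-like study spanning 1-200 ppm.
#' Backgrounds differ by strain while the curve shape is shared; the true
#' CEDs default to the order of magnitude of published benzene MN potency
#' (~10 ppm) but are arbitrary choices, not estimates from any real study.
#'
#' @param seed integer seed (the second study uses `seed + 1`).
#' @param n_do,n_b6 animals per group in the two studies.
#' @param truth_do,truth_b6 [dr_params] ground truths per strain.
#' @param ces critical effect size (default 0.5).
#' @return a named list of two individual-mode [dr_dataset] objects
#'   (`DO`, `B6C3F1`), each carrying its truth attributes.
#' @export
benzene_like_fixture <- function(seed, n_do = 75, n_b6 = 10,
                                 truth_do = dr_params("exponential",
                                                      a = 0.25, ced = 10,
                                                      c = 15, d = 1,
                                                      log_sd = 0.4),
                                 truth_b6 = dr_params("exponential",
                                                      a = 0.15, ced = 8,
                                                      c = 15, d = 1,
                                                      log_sd = 0.4),
                                 ces = 0.5) {
  do_design <- study_design(c(0, 1, 10, 100), n_do, covariate_label = "DO",
                            hours_per_day = 6, days_per_week = 5, weeks = 4)
  b6_design <- study_design(c(0, 1, 5, 10, 100, 200), n_b6,
                            covariate_label = "B6C3F1",
                            hours_per_day = 6, days_per_week = 5, weeks = 4)
  list(DO = generate_study(do_design, truth_do, seed, ces = ces),
       B6C3F1 = generate_study(b6_design, truth_b6, seed + 1, ces = ces))
}
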