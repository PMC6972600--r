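# shared fixtures built in code; all randomness goes through explicit seeds

# small single-strain study for fast fits
tiny_truth <- function(log_sd = 0.35) {
  dr_params("exponential", a = 0.3, ced = 12, c = 8, d = 1, log_sd = log_sd)
}

tiny_design <- function(n = 8) {
  study_design(c(0, 2, 5, 15, 50, 150), n, covariate_label = "S1")
}

tiny_study <- function(seed = 11, n = 8, log_sd = 0.35) {
  generate_study(tiny_design(n), tiny_truth(log_sd), seed = seed)
}

# random valid parameter draw for property tests (seeded by caller)
random_params <- function() {
  family <- sample(c("exponential", "hill"), 1)
  ces <- 0.5
  c <- 1 + ces + exp(stats::runif(1, log(0.2), log(50)))
  dr_params(family,
            a = exp(stats::runif(1, log(0.05), log(5))),
            ced = exp(stats::runif(1, log(0.5), log(50))),
            c = c,
            d = exp(stats::runif(1, log(0.3), log(3))),
            log_sd = stats::runif(1, 0.1, 0.8))
}

# two-strain dataset from the generator defaults, concatenated for fitting
two_strain_dataset <- function(seed) {
  fix <- benzene_like_fixture(seed)
  d1 <- fix$DO$data
  d2 <- fix$B6C3F1$data
  dr_dataset(rbind(d1, d2))
}
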