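#' Lognormal log-likelihood of a dose-response dataset
#'
#' Evaluates the log-likelihood of `data` under a single parameter set: the
#' log responses are modelled as Normal with mean `log(dr_predict(dose))`
#' and standard deviation `log_sd` (the Jacobian constant of the log
#' transform is omitted, so data equal to the model medians give exactly
#' `-(N/2) * log(2 * pi * log_sd^2)`). Summary-mode groups enter through
#' the method-of-moments log-scale transform of their arithmetic mean and
#' SD. The result is additive over groups and invariant to group order.
#'
#' @param params a [dr_params] object (applied to every group).
#' @param ces critical effect size defining the CED.
#' @param data a [dr_dataset].
#' @param offset optional additive offset applied to responses before the
#'   log transform; default 0 (non-positive responses are then an error).
#' @return scalar log-likelihood.
#' @export
dr_loglik <- function(params, ces, data, offset = 0) {
  stopifnot(inherits(params, "dr_params"), inherits(data, "dr_dataset"))
  check_ces(ces, params$c)
  st <- suff_stats(data, offset = offset)
  mu <- predict_vec(params$family, params$a, params$ced, params$c, params$d,
                    ces, st$dose)
  loglik_stats(st, log(mu), params$log_sd)
}

# core normal log-likelihood on the log scale from sufficient statistics;
# lmu and sd may be scalars or per-row vectors
loglik_stats <- function(st, lmu, sd) {
  sum(-st$n / 2 * log(2 * pi * sd^2) -
        (st$ss + st$n * (st$mlog - lmu)^2) / (2 * sd^2))
}
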