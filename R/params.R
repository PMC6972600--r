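#' Continuous dose-response model parameters
#'
#' Container for a single parameter set of the four-parameter exponential
#' (Slob model 5) or Hill continuous dose-response model, parameterised
#' directly in the critical effect dose (CED) rather than the rate /
#' half-maximum parameter `b`, so that the benchmark concentration is a
#' model parameter and profile likelihood operates on it directly.
#'
#' The model median response at dose \eqn{x} is
#' \deqn{exponential: y(x) = a\,[c - (c-1)\exp(-b x^d)]}
#' \deqn{Hill: y(x) = a\,[1 + (c-1) x^d / (b^d + x^d)]}
#' with `b` recovered from the CED at a stated critical effect size (CES),
#' see [b_from_ced()].
#'
#' @param family `"exponential"` or `"hill"`.
#' @param a background (control) median response, response units; `> 0`.
#' @param ced critical effect dose, dose units (ppm); `> 0`.
#' @param c maximum fold change over background (dimensionless); `> 1`
#'   for an increasing endpoint.
#' @param d log-steepness (dimensionless); `> 0`.
#' @param log_sd residual standard deviation of log response; `> 0`.
#'
#' @return An object of class `dr_params`.
#' @examples
#' p <- dr_params("exponential", a = 0.25, ced = 10, c = 15, d = 1, log_sd = 0.4)
#' dr_predict(p, dose = c(0, 10, 100), ces = 0.5)
#' @export
dr_params <- function(family = c("exponential", "hill"), a, ced, c, d,
                      log_sd = 0.3) {
  family <- match.arg(family)
  for (nm in c("a", "ced", "c", "d", "log_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a finite numeric scalar", call. = FALSE)
  }
  if (a <= 0) stop("background 'a' must be > 0", call. = FALSE)
  if (ced <= 0) stop("'ced' must be > 0", call. = FALSE)
  if (c <= 1) stop("maximum fold change 'c' must be > 1 (increasing endpoint)",
                   call. = FALSE)
  if (d <= 0) stop("log-steepness 'd' must be > 0", call. = FALSE)
  if (log_sd <= 0) stop("'log_sd' must be > 0", call. = FALSE)
  structure(list(family = family, a = a, ced = ced, c = c, d = d,
                 log_sd = log_sd),
            class = "dr_params")
}

#' @export
print.dr_params <- function(x, ...) {
  cat(sprintf("%s dose-response parameters: a=%.4g, CED=%.4g, c=%.4g, d=%.4g, log SD=%.4g\n",
              x$family, x$a, x$ced, x$c, x$d, x$log_sd))
  invisible(x)
}

check_ces <- function(ces, c = NULL) {
  if (!is.numeric(ces) || length(ces) != 1L || !is.finite(ces) || ces <= 0)
    stop("'ces' must be a positive scalar (fractional increase over background)",
         call. = FALSE)
  if (!is.null(c) && ces >= c - 1)
    stop("CED undefined: ces (", ces, ") must be < c - 1 (", c - 1,
         "); the curve never reaches a (1 + ces)-fold response", call. = FALSE)
  invisible(ces)
}

#' Rate / half-maximum parameter from the critical effect dose
#'
#' Solves \eqn{y(CED) = a (1 + CES)} for the conventional `b` parameter of
#' the exponential or Hill family. For the exponential model
#' \eqn{b = -\log((c-1-ces)/(c-1)) / ced^d}; for the Hill model
#' \eqn{b = ced\,((c-1-ces)/ces)^{1/d}} (the half-maximum dose).
#'
#' @param params a [dr_params] object.
#' @param ces critical effect size, fractional increase over background;
#'   must satisfy `ces < c - 1` or the CED is undefined.
#' @return the scalar `b` on the dose scale (Hill) or inverse-dose^d scale
#'   (exponential).
#' @export
b_from_ced <- function(params, ces) {
  stopifnot(inherits(params, "dr_params"))
  check_ces(ces, params$c)
  b_from_ced_vec(params$family, params$ced, params$c, params$d, ces)
}

# vectorised internals used by the fitting layer: a/ced may be per-group
b_from_ced_vec <- function(family, ced, c, d, ces) {
  if (family == "exponential") {
    -log((c - 1 - ces) / (c - 1)) / ced^d
  } else {
    ced * ((c - 1 - ces) / ces)^(1 / d)
  }
}

predict_vec <- function(family, a, ced, c, d, ces, dose) {
  b <- b_from_ced_vec(family, ced, c, d, ces)
  xd <- dose^d
  if (family == "exponential") {
    a * (c - (c - 1) * exp(-b * xd))
  } else {
    a * (1 + (c - 1) * xd / (b^d + xd))
  }
}

#' Median response at a dose under the CED parameterisation
#'
#' Evaluates the model median response. By construction `dr_predict(p, 0)`
#' equals the background `a`, `dr_predict(p, p$ced)` equals
#' `a * (1 + ces)`, and the curve increases towards the plateau `a * c`.
#'
#' @param params a [dr_params] object.
#' @param dose numeric vector of doses, `>= 0` (ppm).
#' @param ces critical effect size defining the CED (e.g. `0.5` for a 50%
#'   increase over background).
#' @return numeric vector of median responses (response units).
#' @export
dr_predict <- function(params, dose, ces) {
  stopifnot(inherits(params, "dr_params"))
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("doses must be finite and >= 0", call. = FALSE)
  check_ces(ces, params$c)
  predict_vec(params$family, params$a, params$ced, params$c, params$d, ces, dose)
}
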