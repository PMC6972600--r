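#' Covariate structure for joint dose-response fitting
#'
#' Declares which parameters are allowed to differ between covariate levels
#' (strains / studies) in a joint fit. The shape parameters `c`
#' (maximum fold change) and `d` (log-steepness) are always shared; the
#' background `a`, the potency `ced` and optionally the residual `log_sd`
#' may split by covariate.
#'
#' @param a_split background `a` per covariate level?
#' @param ced_split CED per covariate level?
#' @param log_sd_split residual log-scale SD per covariate level?
#' @return an object of class `covariate_config`.
#' @export
covariate_config <- function(a_split = TRUE, ced_split = TRUE,
                             log_sd_split = FALSE) {
  structure(list(a_split = isTRUE(a_split), ced_split = isTRUE(ced_split),
                 log_sd_split = isTRUE(log_sd_split)),
            class = "covariate_config")
}

config_label <- function(cfg) {
  split <- c("a"[cfg$a_split], "CED"[cfg$ced_split], "logSD"[cfg$log_sd_split])
  if (!length(split)) "all shared" else paste(split, collapse = "+")
}

# Internal fitting specification: maps the free parameter vector theta (all
# on the log scale) to natural parameters and exposes the negative
# log-likelihood with box bounds. `fix_ced` pins one CED entry (profile
# likelihood); `fixed` pins c and/or d (nested sub-models).
make_fitspec <- function(stats, family, ces, config, fixed = list(),
                         fix_ced_idx = NULL, fix_ced_value = NULL) {
  levels <- sort(unique(stats$covariate))
  L <- length(levels)
  lvl <- match(stats$covariate, levels)

  na <- if (config$a_split) L else 1L
  nced <- if (config$ced_split) L else 1L
  nsd <- if (config$log_sd_split) L else 1L
  a_of <- if (config$a_split) seq_len(L) else rep(1L, L)
  ced_of <- if (config$ced_split) seq_len(L) else rep(1L, L)
  sd_of <- if (config$log_sd_split) seq_len(L) else rep(1L, L)

  c_free <- is.null(fixed$c)
  d_free <- is.null(fixed$d)
  if (!c_free) check_ces(ces, fixed$c)

  gm <- exp(stats$mlog)
  pos <- stats$dose[stats$dose > 0]
  if (!length(pos)) stop("need at least one positive dose", call. = FALSE)
  a_rng <- c(min(gm) / 20, max(gm) * 20)
  ced_rng <- c(min(pos) / 50, max(stats$dose) * 50)
  cm1_rng <- c(1e-3, 1e3)          # c - 1 - ces
  d_rng <- c(0.25, 4)              # steepness guard on sparse designs
  sd_rng <- c(1e-3, 5)

  free_ced <- setdiff(seq_len(nced), fix_ced_idx)
  nm <- c(paste0("a", seq_len(na)),
          if (length(free_ced)) paste0("ced", free_ced),
          if (c_free) "cm1", if (d_free) "d", paste0("sd", seq_len(nsd)))
  lower <- log(c(rep(a_rng[1], na), rep(ced_rng[1], length(free_ced)),
                 if (c_free) cm1_rng[1], if (d_free) d_rng[1],
                 rep(sd_rng[1], nsd)))
  upper <- log(c(rep(a_rng[2], na), rep(ced_rng[2], length(free_ced)),
                 if (c_free) cm1_rng[2], if (d_free) d_rng[2],
                 rep(sd_rng[2], nsd)))
  names(lower) <- names(upper) <- nm

  i_a <- seq_len(na)
  i_ced <- na + seq_along(free_ced)
  i_c <- if (c_free) na + length(free_ced) + 1L else integer(0)
  i_d <- if (d_free) na + length(free_ced) + length(i_c) + 1L else integer(0)
  i_sd <- na + length(free_ced) + length(i_c) + length(i_d) + seq_len(nsd)

  unpack <- function(theta) {
    ced <- numeric(nced)
    ced[free_ced] <- exp(theta[i_ced])
    if (!is.null(fix_ced_idx)) ced[fix_ced_idx] <- fix_ced_value
    list(a = exp(theta[i_a]), ced = ced,
         c = if (c_free) unname(1 + ces + exp(theta[i_c])) else fixed$c,
         d = if (d_free) unname(exp(theta[i_d])) else fixed$d,
         sd = exp(theta[i_sd]))
  }

  negll <- function(theta) {
    p <- unpack(theta)
    mu <- predict_vec(family, p$a[a_of][lvl], p$ced[ced_of][lvl], p$c, p$d,
                      ces, stats$dose)
    if (!all(is.finite(mu)) || any(mu <= 0)) return(1e10)
    ll <- loglik_stats(stats, log(mu), p$sd[sd_of][lvl])
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  list(stats = stats, levels = levels, family = family, ces = ces,
       config = config, fixed = fixed, a_of = a_of, ced_of = ced_of,
       sd_of = sd_of, unpack = unpack, negll = negll,
       lower = lower, upper = upper, k = length(lower),
       fix_ced_idx = fix_ced_idx)
}

# run RNG-dependent code under a temporary seed, restoring global state
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

optim_spec <- function(spec, start, maxit = 300) {
  tryCatch(
    stats::optim(start, spec$negll, method = "L-BFGS-B",
                 lower = spec$lower, upper = spec$upper,
                 control = list(maxit = maxit)),
    error = function(e) list(par = start, value = spec$negll(start),
                             convergence = 99L, message = conditionMessage(e))
  )
}

# multi-start maximisation: Latin-hypercube starts over the log-parameter
# box plus the box centre (and an optional warm start)
multistart_optim <- function(spec, n_starts, seed, warm = NULL) {
  k <- spec$k
  u <- with_local_seed(seed, lhs::randomLHS(max(n_starts, 1L), k))
  starts <- t(spec$lower + t(u) * (spec$upper - spec$lower))
  starts <- rbind((spec$lower + spec$upper) / 2, starts)
  if (!is.null(warm)) starts <- rbind(pmin(pmax(warm, spec$lower),
                                           spec$upper), starts)
  best <- NULL
  codes <- integer(nrow(starts))
  for (i in seq_len(nrow(starts))) {
    res <- optim_spec(spec, starts[i, ])
    codes[i] <- res$convergence
    if (is.null(best) || res$value < best$value) {
      best <- res
      best$start_idx <- i
    }
  }
  best$codes <- codes
  best
}

#' Fit a continuous dose-response model by constrained maximum likelihood
#'
#' Joint lognormal maximum-likelihood fit of the exponential or Hill family
#' with CED parameterisation, covariate-dependent background/potency per
#' `config`, box constraints on all parameters (log-transformed
#' internally; steepness `d` is restricted to \[0.25, 4\]) and
#' Latin-hypercube multi-start local optimisation, deterministic for a
#' given `seed`.
#'
#' @param data a [dr_dataset]; each covariate level needs at least 3
#'   distinct doses.
#' @param family `"exponential"` or `"hill"`.
#' @param ces critical effect size (fractional increase over background)
#'   defining the CED, e.g. `0.5`.
#' @param config a [covariate_config()].
#' @param n_starts number of Latin-hypercube starts (the box centre is
#'   always added).
#' @param seed integer seed for the start design.
#' @param fixed optional list pinning `c` and/or `d` (nested sub-models).
#' @param offset optional additive response offset (recorded in the fit).
#' @return an object of class `dr_fit` with elements `params` (per-level
#'   `a`, `ced`; shared `c`, `d`; `log_sd`), `log_lik`, `n_free_params`,
#'   `aic` (`= 2 k - 2 logLik`) and `diagnostics`.
#' @export
fit_dr_model <- function(data, family = c("exponential", "hill"), ces,
                         config = covariate_config(), n_starts = 20,
                         seed = 1, fixed = list(), offset = 0) {
  stopifnot(inherits(data, "dr_dataset"))
  family <- match.arg(family)
  check_ces(ces)
  st <- suff_stats(data, offset = offset)
  ndose <- tapply(st$dose, st$covariate, function(x) length(unique(x)))
  if (any(ndose < 3))
    stop("fewer than 3 distinct doses for covariate level(s): ",
         paste(names(ndose)[ndose < 3], collapse = ", "), call. = FALSE)

  spec <- make_fitspec(st, family, ces, config, fixed = fixed)
  best <- multistart_optim(spec, n_starts, seed)
  if (all(best$codes != 0L) || !is.finite(best$value) || best$value >= 1e10)
    stop("model fit failed to converge from any of ", length(best$codes),
         " starts (family=", family, ", structure=", config_label(config),
         ")", call. = FALSE)

  p <- spec$unpack(best$par)
  L <- spec$levels
  params <- list(
    a = stats::setNames(p$a[spec$a_of][seq_along(L)], L),
    ced = stats::setNames(p$ced[spec$ced_of][seq_along(L)], L),
    c = p$c, d = p$d,
    log_sd = stats::setNames(p$sd[spec$sd_of][seq_along(L)], L))
  k <- spec$k
  ll <- -best$value
  structure(list(
    family = family, ces = ces, config = config, fixed = fixed,
    offset = offset, params = params, levels = L,
    log_lik = ll, n_free_params = k, aic = 2 * k - 2 * ll,
    theta_hat = best$par, stats = st,
    bounds = list(lower = spec$lower, upper = spec$upper),
    diagnostics = list(n_starts = n_starts, seed = seed,
                       best_start = best$start_idx,
                       convergence = best$convergence,
                       start_codes = best$codes)),
    class = "dr_fit")
}

#' @export
print.dr_fit <- function(x, ...) {
  cat(sprintf("%s model fit (CES = %g): logLik = %.4f, k = %d, AIC = %.4f\n",
              x$family, x$ces, x$log_lik, x$n_free_params, x$aic))
  cat(sprintf("  covariate structure: %s\n", config_label(x$config)))
  for (l in x$levels)
    cat(sprintf("  [%s] a = %.4g, CED = %.4g ppm\n", l,
                x$params$a[[l]], x$params$ced[[l]]))
  cat(sprintf("  shared c = %.4g, d = %.4g, log SD = %s\n", x$params$c,
              x$params$d, paste(signif(unique(x$params$log_sd), 4),
                                collapse = "/")))
  invisible(x)
}

#' Select the covariate structure by AIC
#'
#' Fits the lattice of covariate structures — all parameters shared;
#' background `a` split; `a` + CED split; `a` + CED + residual SD split —
#' and returns the lowest-AIC fit. Fits within 2 AIC units of the minimum
#' are treated as ties and resolved towards fewer free parameters. All
#' candidate AICs are retained in `$covariate_selection`.
#'
#' @inheritParams fit_dr_model
#' @return the selected `dr_fit`, with a `covariate_selection` data.frame
#'   (structure, n_free_params, log_lik, aic, selected) attached.
#' @export
select_covariate_structure <- function(data, family = c("exponential", "hill"),
                                       ces, n_starts = 20, seed = 1,
                                       offset = 0) {
  stopifnot(inherits(data, "dr_dataset"))
  family <- match.arg(family)
  levels <- unique(data$data$covariate)
  if (length(levels) < 2) {
    fit <- fit_dr_model(data, family, ces,
                        config = covariate_config(FALSE, FALSE, FALSE),
                        n_starts = n_starts, seed = seed, offset = offset)
    fit$covariate_selection <- data.frame(
      structure = "all shared", n_free_params = fit$n_free_params,
      log_lik = fit$log_lik, aic = fit$aic, selected = TRUE)
    return(fit)
  }
  candidates <- list(
    covariate_config(FALSE, FALSE, FALSE),
    covariate_config(TRUE, FALSE, FALSE),
    covariate_config(TRUE, TRUE, FALSE),
    covariate_config(TRUE, TRUE, TRUE))
  fits <- vector("list", length(candidates))
  errs <- character(0)
  for (i in seq_along(candidates)) {
    fits[[i]] <- tryCatch(
      fit_dr_model(data, family, ces, config = candidates[[i]],
                   n_starts = n_starts, seed = seed, offset = offset),
      error = function(e) {
        errs <<- c(errs, conditionMessage(e))
        NULL
      })
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop("all covariate structures failed to fit: ",
         paste(unique(errs), collapse = "; "), call. = FALSE)
  aic <- vapply(fits[ok], `[[`, numeric(1), "aic")
  k <- vapply(fits[ok], `[[`, numeric(1), "n_free_params")
  near <- which(aic < min(aic) + 2)               # ties within 2 AIC units
  pick <- near[order(k[near], aic[near])][1]
  best <- fits[ok][[pick]]
  tab <- data.frame(
    structure = vapply(candidates[ok], config_label, character(1)),
    n_free_params = k,
    log_lik = vapply(fits[ok], `[[`, numeric(1), "log_lik"),
    aic = aic,
    selected = seq_along(aic) == pick)
  best$covariate_selection <- tab
  best
}
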