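#' Round half-up to a number of significant figures
#'
#' Reporting convention for the risk-characterization chain: every reported
#' intermediate (human-equivalent PoD, acceptable exposure bound) is
#' rounded half-up to 2 significant figures, and the rounded value feeds
#' the next reported step. Unlike [signif()], exact halves round away from
#' zero (3.55 -> 3.6); a small relative guard keeps halves that fall just
#' short in binary floating point (14.2/4) on the upper side.
#'
#' @param x numeric vector.
#' @param digits significant figures (default 2).
#' @return rounded numeric vector.
#' @export
signif_half_up <- function(x, digits = 2) {
  round_one <- function(xi) {
    if (!is.finite(xi) || xi == 0) return(xi)
    s <- sign(xi)
    ax <- abs(xi)
    k <- (digits - 1L) - floor(log10(ax))
    p <- 10^abs(k)
    # final op is a correctly-rounded division (or exact integer multiply)
    # so results land on the decimal literal, e.g. 3.55 -> 3.6 exactly
    m <- if (k >= 0) floor(ax * p + 0.5 + 1e-8) else floor(ax / p + 0.5 + 1e-8)
    s * (if (k >= 0) m / p else m * p)
  }
  vapply(x, round_one, numeric(1))
}

MW_BENZENE <- 78.11       # g/mol
MOLAR_VOLUME_20C <- 24.04 # L/mol at 20 degC, 101.3 kPa

#' Gas-phase concentration unit conversions
#'
#' Ideal-gas conversions between volume-mixing-ratio units (ppm, ppb) and
#' mass-concentration units (mg/m3, ug/m3):
#' `mg/m3 = ppm * MW / Vm` with molecular weight `MW` (g/mol) and molar
#' volume `Vm` (L/mol). Defaults are benzene (78.11 g/mol) at 20 degC and
#' 101.3 kPa (24.04 L/mol). Full precision is kept internally; rounding is
#' a reporting decision ([signif_half_up()]).
#'
#' @param c concentration (ppm, mg/m3, ug/m3 or ppb as named), `>= 0`.
#' @param mw molecular weight, g/mol.
#' @param molar_volume molar volume, L/mol.
#' @return converted concentration.
#' @examples
#' signif_half_up(ppm_to_mgm3(0.05))  # 0.16 mg/m3
#' signif_half_up(ugm3_to_ppb(5))     # 1.5 ppb
#' @export
ppm_to_mgm3 <- function(c, mw = MW_BENZENE, molar_volume = MOLAR_VOLUME_20C) {
  check_conc(c, mw, molar_volume)
  c * mw / molar_volume
}

#' @rdname ppm_to_mgm3
#' @export
mgm3_to_ppm <- function(c, mw = MW_BENZENE, molar_volume = MOLAR_VOLUME_20C) {
  check_conc(c, mw, molar_volume)
  c * molar_volume / mw
}

#' @rdname ppm_to_mgm3
#' @export
ugm3_to_ppb <- function(c, mw = MW_BENZENE, molar_volume = MOLAR_VOLUME_20C) {
  mgm3_to_ppm(c, mw, molar_volume)   # ug/m3 -> ppb has the same factor
}

#' @rdname ppm_to_mgm3
#' @export
ppb_to_ugm3 <- function(c, mw = MW_BENZENE, molar_volume = MOLAR_VOLUME_20C) {
  ppm_to_mgm3(c, mw, molar_volume)
}

check_conc <- function(c, mw, molar_volume) {
  if (any(!is.finite(c)) || any(c < 0))
    stop("concentration must be finite and >= 0", call. = FALSE)
  if (mw <= 0 || molar_volume <= 0)
    stop("molecular weight and molar volume must be > 0", call. = FALSE)
  invisible(c)
}

#' Point-of-departure range
#'
#' An ordered dose range (e.g. BMCL to BMCU of a benchmark-concentration
#' analysis) carried through the risk-characterization chain.
#'
#' @param lower,upper bounds in ppm, `0 < lower <= upper`.
#' @param basis free-text provenance, e.g. `"BMCL50/BMCU50, MN-RET, DO mouse"`.
#' @return an object of class `pod_range`.
#' @export
pod_range <- function(lower, upper, basis = "") {
  if (!is.finite(lower) || !is.finite(upper) || lower <= 0 || lower > upper)
    stop("need 0 < lower <= upper for a PoD range", call. = FALSE)
  structure(list(lower = lower, upper = upper, basis = basis),
            class = "pod_range")
}

#' Exposure-regimen adjustment for human-equivalent conversion
#'
#' Hour and inhaled-volume terms converting an animal air-concentration
#' PoD to a human-equivalent value:
#' `PoD_HE = PoD * (animal_hours / human_hours) * (animal_volume / human_volume)`.
#'
#' [worker_adjustment()] uses the occupational defaults (animals 6 h/day vs
#' an 8-h shift; light-activity equivalent inhaled volume 6.7 m3 scaled to
#' 10 m3 for working activity). [general_population_adjustment()] assumes
#' round-the-clock exposure (6/24) with activity similar to the animals
#' (volume ratio 1).
#'
#' @param animal_hours,human_hours exposure hours per day, `0 < h <= 24`.
#' @param animal_volume,human_volume equivalent inhaled air volumes (m3),
#'   `> 0`.
#' @return an object of class `exposure_adjustment`.
#' @export
exposure_adjustment <- function(animal_hours, human_hours,
                                animal_volume = 1, human_volume = 1) {
  vals <- c(animal_hours, human_hours, animal_volume, human_volume)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all adjustment terms must be finite and > 0", call. = FALSE)
  if (animal_hours > 24 || human_hours > 24)
    stop("hours per day cannot exceed 24", call. = FALSE)
  structure(list(animal_hours = animal_hours, human_hours = human_hours,
                 animal_volume = animal_volume, human_volume = human_volume),
            class = "exposure_adjustment")
}

#' @rdname exposure_adjustment
#' @export
worker_adjustment <- function() {
  exposure_adjustment(animal_hours = 6, human_hours = 8,
                      animal_volume = 6.7, human_volume = 10)
}

#' @rdname exposure_adjustment
#' @export
general_population_adjustment <- function() {
  exposure_adjustment(animal_hours = 6, human_hours = 24,
                      animal_volume = 1, human_volume = 1)
}

#' Human-equivalent point of departure
#'
#' Scales each PoD bound by the hour ratio and inhaled-volume ratio of the
#' adjustment, then (by default) rounds to 2 significant figures half-up —
#' the reported value that feeds the acceptable-range step.
#'
#' @param pod a [pod_range()] in ppm.
#' @param adj an [exposure_adjustment()].
#' @param rounded apply the 2-significant-figure reporting rounding
#'   (default `TRUE`; set `FALSE` for full precision).
#' @return a `pod_range` in ppm.
#' @examples
#' human_equivalent_pod(pod_range(9.6, 14.2), worker_adjustment())
#' @export
human_equivalent_pod <- function(pod, adj, rounded = TRUE) {
  stopifnot(inherits(pod, "pod_range"), inherits(adj, "exposure_adjustment"))
  r <- (adj$animal_hours / adj$human_hours) *
    (adj$animal_volume / adj$human_volume)
  lo <- pod$lower * r
  hi <- pod$upper * r
  if (rounded) {
    lo <- signif_half_up(lo)
    hi <- signif_half_up(hi)
  }
  pod_range(lo, hi, basis = paste0(pod$basis,
                                   sprintf(" [x %.4g/%.4g h x %.4g/%.4g m3]",
                                           adj$animal_hours, adj$human_hours,
                                           adj$animal_volume,
                                           adj$human_volume)))
}

#' Assessment-factor set and composite factor
#'
#' A set of multiplicative assessment factors (AFs), each with a rationale
#' category; the composite AF is their product. AF choices are
#' case-specific expert input, never package policy: the benzene worker
#' preset (2.5 interspecies TK/TD x 6 duration x 5 intraspecies x 3
#' severity = 225) and general-population preset (2.5 x 6 x 10 x 3 = 450)
#' ship as illustrative configurations and should not be read as setting a
#' precedent.
#'
#' @param values numeric factors, `> 0` (values below 1 draw a warning).
#' @param rationales character vector, recycled, drawn from
#'   `interspecies_tk_td`, `duration`, `intraspecies`, `severity`, `other`.
#' @param notes optional free-text per factor.
#' @return an object of class `af_set` (data.frame of value/rationale/note).
#' @export
assessment_factors <- function(values,
                               rationales = "other",
                               notes = "") {
  if (!length(values)) {
    return(structure(data.frame(value = numeric(0), rationale = character(0),
                                note = character(0)),
                     class = c("af_set", "data.frame")))
  }
  allowed <- c("interspecies_tk_td", "duration", "intraspecies", "severity",
               "other")
  rationales <- rep_len(as.character(rationales), length(values))
  notes <- rep_len(as.character(notes), length(values))
  if (!all(rationales %in% allowed))
    stop("rationale must be one of: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(values) | values <= 0))
    stop("assessment factors must be finite and > 0", call. = FALSE)
  if (any(values < 1))
    warning("assessment factor below 1: ",
            paste(values[values < 1], collapse = ", "))
  structure(data.frame(value = values, rationale = rationales, note = notes,
                       stringsAsFactors = FALSE),
            class = c("af_set", "data.frame"))
}

#' @rdname assessment_factors
#' @export
benzene_worker_afs <- function() {
  assessment_factors(
    values = c(2.5, 6, 5, 3),
    rationales = c("interspecies_tk_td", "duration", "intraspecies",
                   "severity"),
    notes = c("interspecies variability in toxicokinetics/toxicodynamics",
              "28-day study to chronic exposure",
              "intraspecies variability, workers",
              "severity of the effect"))
}

#' @rdname assessment_factors
#' @export
benzene_general_afs <- function() {
  assessment_factors(
    values = c(2.5, 6, 10, 3),
    rationales = c("interspecies_tk_td", "duration", "intraspecies",
                   "severity"),
    notes = c("interspecies variability in toxicokinetics/toxicodynamics",
              "28-day study to chronic exposure",
              "intraspecies variability, general population",
              "severity of the effect"))
}

#' @rdname assessment_factors
#' @param afs an `af_set`.
#' @export
compose_afs <- function(afs) {
  stopifnot(inherits(afs, "af_set"))
  if (!nrow(afs)) {
    warning("empty assessment-factor set; composite AF = 1")
    return(1)
  }
  prod(afs$value)
}

#' Acceptable daily exposure range
#'
#' Divides each (reported, 2-significant-figure) human-equivalent PoD
#' bound by the composite assessment factor, converts ppm to ppb (x1000)
#' and rounds the result to 2 significant figures half-up.
#'
#' @param pod_he human-equivalent [pod_range()] in ppm (already at
#'   reporting precision).
#' @param composite_af composite assessment factor, `> 0`.
#' @return list with `lower`, `upper` (ppb) and `units`.
#' @examples
#' acceptable_range(pod_range(4.8, 7.1), 225)  # 21-32 ppb
#' @export
acceptable_range <- function(pod_he, composite_af) {
  stopifnot(inherits(pod_he, "pod_range"))
  if (!is.finite(composite_af) || composite_af <= 0)
    stop("composite assessment factor must be > 0", call. = FALSE)
  list(lower = signif_half_up(pod_he$lower / composite_af * 1000),
       upper = signif_half_up(pod_he$upper / composite_af * 1000),
       units = "ppb")
}

#' Margin of exposure
#'
#' Ratio of a point of departure to an exposure estimate (same units).
#' For benzene the case study reports the traditional acceptable-level
#' comparison rather than applying the MOE concept (the genotoxicity is
#' considered secondary in nature); the helper is provided for endpoints
#' where MOE is the chosen metric.
#'
#' @param pod point of departure (scalar).
#' @param exposure exposure estimate (scalar, `> 0`, same units as `pod`).
#' @return dimensionless MOE.
#' @export
margin_of_exposure <- function(pod, exposure) {
  if (!is.finite(exposure) || exposure <= 0)
    stop("MOE undefined: exposure must be > 0", call. = FALSE)
  if (!is.finite(pod) || pod <= 0)
    stop("PoD must be > 0", call. = FALSE)
  pod / exposure
}

#' Compare an exposure range with an acceptable range
#'
#' Verdict rule: `"above"` if the exposure lower bound exceeds the
#' acceptable upper bound; `"below"` if the exposure upper bound is under
#' the acceptable lower bound; otherwise `"within"` (overlapping). An
#' exposure exactly at a boundary counts as overlapping.
#'
#' @param acceptable,exposure lists or numeric length-2 vectors with
#'   ordered `lower`/`upper` bounds, in the same units (ppb).
#' @return `"above"`, `"below"` or `"within"`.
#' @export
characterize_risk <- function(acceptable, exposure) {
  acc <- as_bounds(acceptable, "acceptable")
  exp_ <- as_bounds(exposure, "exposure")
  if (exp_[1] > acc[2]) "above"
  else if (exp_[2] < acc[1]) "below"
  else "within"
}

as_bounds <- function(x, what) {
  if (is.list(x)) x <- c(x$lower, x$upper)
  x <- as.numeric(x)
  if (length(x) == 1) x <- c(x, x)
  if (length(x) != 2 || any(!is.finite(x)) || x[1] > x[2])
    stop("'", what, "' must be an ordered lower/upper pair", call. = FALSE)
  x
}

#' Aggregate exposure over sources
#'
#' Sums exposure contributions (ppb) over sources (ambient air, smoking,
#' refuelling, ...), retaining the per-source breakdown.
#'
#' @param sources data.frame with columns `label` and `level` (ppb,
#'   `>= 0`), or a named numeric vector.
#' @return list with `total` (ppb) and `breakdown` (data.frame).
#' @export
aggregate_exposure <- function(sources) {
  if (is.numeric(sources))
    sources <- data.frame(label = names2(sources), level = as.numeric(sources))
  stopifnot(is.data.frame(sources), all(c("label", "level") %in% names(sources)))
  if (any(!is.finite(sources$level)) || any(sources$level < 0))
    stop("source levels must be finite and >= 0", call. = FALSE)
  list(total = sum(sources$level), breakdown = sources)
}

names2 <- function(x) {
  nm <- names(x)
  if (is.null(nm)) nm <- paste0("source", seq_along(x))
  nm[nm == ""] <- paste0("source", which(nm == ""))
  nm
}
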