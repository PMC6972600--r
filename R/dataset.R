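#' Dose-response dataset
#'
#' A validated container for continuous dose-response data, either
#' per-animal records (`individual` mode: columns `dose`, `response`,
#' optional `covariate`) or per-group summaries (`summary` mode: columns
#' `dose`, `n`, `mean`, `sd`, optional `covariate`). A dataset never mixes
#' the two modes. Responses are strictly positive frequencies (e.g.
#' micronucleated reticulocytes, %); doses are air concentrations in ppm
#' unless relabelled.
#'
#' @param data a data.frame in one of the two dialects above.
#' @param endpoint free-text endpoint label.
#' @param dose_units,response_units unit labels; the fitting layer never
#'   converts units and refuses to combine datasets whose labels differ.
#' @return An object of class `dr_dataset` with elements `data`, `mode`,
#'   `endpoint`, `dose_units`, `response_units`.
#' @examples
#' d <- data.frame(dose = c(0, 1, 10, 100), n = 5,
#'                 mean = c(0.25, 0.26, 0.4, 2.9), sd = c(0.1, 0.1, 0.15, 1.1))
#' dr_dataset(d)
#' @export
dr_dataset <- function(data, endpoint = "micronucleated reticulocytes",
                       dose_units = "ppm", response_units = "%") {
  data <- as.data.frame(data)
  has_ind <- "response" %in% names(data)
  has_sum <- all(c("n", "mean", "sd") %in% names(data))
  if (has_ind && any(c("n", "mean", "sd") %in% names(data)))
    stop("mixed dialect: data has both 'response' and summary columns",
         call. = FALSE)
  if (!has_ind && !has_sum)
    stop("data must have a 'response' column (individual mode) or ",
         "'n', 'mean', 'sd' columns (summary mode)", call. = FALSE)
  if (!"dose" %in% names(data)) stop("missing 'dose' column", call. = FALSE)
  if (!"covariate" %in% names(data)) data$covariate <- "all"
  data$covariate <- as.character(data$covariate)
  for (col in intersect(c("dose", "response", "mean", "sd"), names(data)))
    data[[col]] <- as.numeric(data[[col]])
  bad <- which(!is.finite(data$dose) | data$dose < 0)
  if (length(bad))
    stop("negative or non-finite dose in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  mode <- if (has_ind) "individual" else "summary"
  if (mode == "individual") {
    bad <- which(!is.finite(data$response))
    if (length(bad))
      stop("non-finite response in row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  } else {
    bad <- which(!is.finite(data$n) | data$n < 1 | data$n != round(data$n))
    if (length(bad))
      stop("group size n must be an integer >= 1; offending row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    bad <- which(!is.finite(data$mean) | data$mean <= 0 |
                   !is.finite(data$sd) | data$sd < 0)
    if (length(bad))
      stop("group mean must be > 0 and sd >= 0; offending row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(data = data, mode = mode, endpoint = endpoint,
                 dose_units = dose_units, response_units = response_units),
            class = "dr_dataset")
}

#' @export
print.dr_dataset <- function(x, ...) {
  lv <- unique(x$data$covariate)
  cat(sprintf("dr_dataset (%s mode): %s [%s] vs dose [%s]\n", x$mode,
              x$endpoint, x$response_units, x$dose_units))
  cat(sprintf("  %d rows, %d dose level(s), covariate level(s): %s\n",
              nrow(x$data), length(unique(x$data$dose)),
              paste(lv, collapse = ", ")))
  invisible(x)
}

#' Collapse an individual-mode dataset to group summaries
#'
#' Replaces per-animal records by per-(dose, covariate) group size,
#' arithmetic mean and SD. `n` and the mean round-trip exactly; the SD is
#' the usual n-1 sample SD.
#'
#' @param dataset a `dr_dataset` (individual mode; summary mode is returned
#'   unchanged).
#' @return a summary-mode `dr_dataset`.
#' @export
as_summary <- function(dataset) {
  stopifnot(inherits(dataset, "dr_dataset"))
  if (dataset$mode == "summary") return(dataset)
  d <- dataset$data
  key <- interaction(d$dose, d$covariate, drop = TRUE)
  agg <- do.call(rbind, lapply(split(d, key), function(g) {
    data.frame(dose = g$dose[1], covariate = g$covariate[1],
               n = nrow(g), mean = mean(g$response),
               sd = if (nrow(g) > 1) stats::sd(g$response) else 0)
  }))
  agg <- agg[order(agg$covariate, agg$dose), ]
  rownames(agg) <- NULL
  dr_dataset(agg, endpoint = dataset$endpoint,
             dose_units = dataset$dose_units,
             response_units = dataset$response_units)
}

# Per-group sufficient statistics on the natural-log response scale.
# Individual mode: n, mean of log y, within-group sum of squares of log y.
# Summary mode: lognormal method-of-moments transform of (mean m, SD s):
#   sigma_log^2 = log(1 + s^2/m^2), mu_log = log(m) - sigma_log^2 / 2,
# with SS = n * sigma_log^2 (mean-squared-deviation convention).
# The normal log-likelihood on the log scale depends on the data only
# through these, so the fitting layer is O(#groups) per evaluation.
suff_stats <- function(dataset, offset = 0) {
  d <- dataset$data
  if (dataset$mode == "individual") {
    y <- d$response + offset
    if (any(y <= 0))
      stop("non-positive response encountered (lognormal model needs y > 0); ",
           "supply a positive 'offset' explicitly if appropriate",
           call. = FALSE)
    key <- interaction(d$dose, d$covariate, drop = TRUE)
    out <- do.call(rbind, lapply(split(log(y), key), function(ly) {
      data.frame(n = length(ly), mlog = mean(ly),
                 ss = sum((ly - mean(ly))^2))
    }))
    meta <- do.call(rbind, lapply(split(d, key), function(g)
      data.frame(dose = g$dose[1], covariate = g$covariate[1])))
    out <- cbind(meta, out)
  } else {
    if (offset != 0) {
      d$mean <- d$mean + offset
    }
    cv2 <- (d$sd / d$mean)^2
    slog2 <- log1p(cv2)
    out <- data.frame(dose = d$dose, covariate = d$covariate, n = d$n,
                      mlog = log(d$mean) - slog2 / 2, ss = d$n * slog2)
  }
  out <- out[order(out$covariate, out$dose), ]
  rownames(out) <- NULL
  out
}

#' Read a dose-response dataset from CSV
#'
#' Accepts either dialect: individual (`dose, response[, covariate]`) or
#' summary (`dose, n, mean, sd[, covariate]`). A file carrying both a
#' `response` column and summary columns is rejected. If a JSON sidecar
#' `<path>.json` exists, endpoint and unit labels are taken from it.
#'
#' @param path CSV file path.
#' @param ... endpoint/unit labels forwarded to [dr_dataset()] (override
#'   the sidecar).
#' @return a `dr_dataset`.
#' @export
read_dr_dataset <- function(path, ...) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  args <- list(...)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    for (nm in c("endpoint", "dose_units", "response_units"))
      if (!is.null(meta[[nm]]) && is.null(args[[nm]])) args[[nm]] <- meta[[nm]]
  }
  do.call(dr_dataset, c(list(data = d), args))
}

#' Write a dose-response dataset to CSV (plus JSON sidecar)
#'
#' The numeric content round-trips exactly through [read_dr_dataset()]
#' (values written at full precision). A sidecar `<path>.json` records
#' endpoint, units and — for simulated data — the generating seed and true
#' parameters.
#'
#' @param dataset a `dr_dataset`.
#' @param path output CSV path.
#' @param sidecar write the JSON sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_dr_dataset <- function(dataset, path, sidecar = TRUE) {
  stopifnot(inherits(dataset, "dr_dataset"))
  df <- dataset$data
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    meta <- list(endpoint = dataset$endpoint, dose_units = dataset$dose_units,
                 response_units = dataset$response_units, mode = dataset$mode)
    tr <- attr(dataset, "truth")
    if (!is.null(tr)) meta$truth <- unclass(tr)
    sd_ <- attr(dataset, "seed")
    if (!is.null(sd_)) meta$seed <- sd_
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}
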