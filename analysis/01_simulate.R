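#!/usr/bin/env Rscript
# Step 1 — simulate the two benzene-like micronucleus inhalation studies.
#
# Generates the synthetic DO-mouse-like study (0/1/10/100 ppm, 75
# animals/group) and B6C3F1-like study (0-200 ppm, 10/group) from the
# lognormal dose-response model, and writes them as CSV with JSON sidecars
# recording the generating truth and seed. These stand in for the
# unpublished MN-RET datasets; their true CEDs (10 and 8 ppm) are
# arbitrary order-of-magnitude choices, not estimates of any real study.

suppressPackageStartupMessages(library(bmdrisk))

seed <- 7
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

fix <- benzene_like_fixture(seed = seed)
for (nm in names(fix)) {
  path <- file.path("results/data", paste0(tolower(nm), "_study.csv"))
  write_dr_dataset(fix[[nm]], path)
  sm <- as_summary(fix[[nm]])
  cat(sprintf("%s study: %d animals, doses %s ppm\n", nm,
              nrow(fix[[nm]]$data),
              paste(unique(fix[[nm]]$data$dose), collapse = "/")))
  print(sm$data)
  write_dr_dataset(sm, file.path("results/data",
                                 paste0(tolower(nm), "_summary.csv")),
                   sidecar = FALSE)
}
cat("\nwrote per-animal and summary CSVs under results/data/\n")
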