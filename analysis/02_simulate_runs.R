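#!/usr/bin/env Rscript
# Step 2: synthetic LC-HRMS run generation.
#
# The study's raw instrument data are not deposited, so screening is
# exercised on seeded synthetic runs that plant the tabulated metabolite
# panels (printed retention times, MAR-proportional areas) with
# instrument-style Gaussian ppm mass error, sodium-adduct twins, noise
# peaks, and isobaric decoys.

suppressPackageStartupMessages(library(silascreen))

seed <- 1L
for (name in c("admb_panel", "cumyl_panel", "isobar_case", "noise_stress")) {
  cfg <- preset(name, seed = seed)
  run <- generate_run(cfg, out_dir = file.path("results/runs", name))
  cat(sprintf("%-12s seed %d: %2d features, %2d spectra, %d decoys -> %s\n",
              name, seed, nrow(run$features), length(run$spectra),
              nrow(cfg$decoys), file.path("results/runs", name)))
}
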