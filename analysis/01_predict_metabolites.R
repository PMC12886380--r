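#!/usr/bin/env Rscript
# Step 1: in silico candidate metabolite prediction.
#
# Enumerates phase I (and, for reference, phase II) candidate metabolites of
# both silicon-containing parents from the biotransformation rule registry,
# and builds the auto-MS/MS inclusion lists a suspect-screening acquisition
# would target. Also writes the silicon-to-carbon swapped analogs used to
# probe structure-based tools that cannot handle silicon.

suppressPackageStartupMessages(library(silascreen))

out_dir <- "results/predict"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

for (parent_name in parent_compound()) {
  p <- parent_compound(parent_name)
  cands <- enumerate_candidates(parent_name, max_steps = 3)
  cat(sprintf("%s (%s, [M+H]+ %.4f): %d candidate compositions/chains (%d phase I, %d phase II)\n",
              parent_name, p$formula, mz(p$formula), nrow(cands),
              sum(cands$phase == "I"), sum(cands$phase == "II")))

  tab <- cands[, c("candidate_key", "chain_class", "formula", "phase",
                   "n_steps", "mass", "mz_[M+H]+", "mz_[M+Na]+")]
  utils::write.csv(tab, file.path(out_dir, paste0(p$label_prefix, "_candidates.csv")),
                   row.names = FALSE)

  incl <- build_inclusion_list(cands[cands$phase == "I", ], ppm_window = 5)
  utils::write.csv(incl, file.path(out_dir, paste0(p$label_prefix, "_inclusion_list.csv")),
                   row.names = FALSE)
  cat(sprintf("  inclusion list: %d targets (m/z %.4f - %.4f)\n",
              nrow(incl), min(incl$mz), max(incl$mz)))

  swapped <- sila_swap(p$smiles)
  cat(sprintf("  Si->C analog: %s (%s)\n",
              format_formula(parse_smiles_min(swapped)), swapped))
}
cat("wrote candidate tables and inclusion lists under", out_dir, "\n")
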