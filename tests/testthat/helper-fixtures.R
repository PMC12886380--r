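# Shared fixtures built in code.

admb <- function() parent_compound("ADMB-3TMS-PrINACA")
cumyl <- function() parent_compound("Cumyl-3TMS-PrINACA")

# Prose-printed accurate masses with their assigned cation compositions.
prose_cations <- function() {
  data.frame(
    formula = c("C3H9Si", "C8H5N2O", "C14H19N2OSi", "C9H11", "C7H7",
                "C9H11O", "C11H11N2O2", "C11H9N2O3", "C8H5N2O2",
                "C14H19N2O2Si", "C19H30N3OSi"),
    mz = c(73.0468, 145.0396, 259.1261, 119.0855, 91.0542,
           135.0804, 203.0815, 217.0608, 161.0346,
           275.1210, 344.2153),
    stringsAsFactors = FALSE
  )
}

# A tiny well-formed feature table.
tiny_features <- function() {
  data.frame(
    sample_id = "urine_1", matrix = "urine",
    rt_min = c(2.97, 7.02, 12.5),
    mz = c(347.1714, 405.2316, 500.2000),
    area = c(50, 100, 25),
    snr = c(10, 20, 8),
    stringsAsFactors = FALSE
  )
}

random_composition <- function() {
  syms <- c("C", "H", "N", "O", "Si", "S", "Cl")
  n <- sample(2:5, 1)
  pick <- sample(syms, n)
  composition(stats::setNames(sample(1:12, n, replace = TRUE), pick))
}
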