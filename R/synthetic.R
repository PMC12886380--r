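#' Synthetic LC-HRMS run configuration
#'
#' Bundles everything [generate_run()] needs to emulate a centroided
#' LC-HRMS suspect-screening run: the planted metabolites (true compositions
#' via candidate chains, retention times, per-sample areas), the relative
#' mass-error model (Gaussian in ppm), uniform-random noise peaks over the
#' acquisition scan range (m/z 50-650), sodium-adduct twins, isobaric decoy
#' features carrying a non-matching fragment set, and a log-normal
#' signal-to-noise model. A single seed controls all randomness; identical
#' config + seed gives byte-identical output files.
#'
#' @param parent_name Parent compound the run is screened against.
#' @param planted Data.frame with columns `chain_class` (canonical chain
#'   class, `""` for the parent itself), `site` (planted biotransformation
#'   site label), `rt_min`, `sample_id`, `matrix`, `area`, `is_parent`.
#' @param decoys Data.frame (possibly empty) with columns `mz`, `rt_min`,
#'   `sample_id`, `matrix`, `area`, `fragments` (list column of fragment
#'   m/z vectors that must not match any expected set).
#' @param mass_error_sd_ppm Standard deviation of the relative mass error
#'   (ppm); 0 gives exact masses.
#' @param noise_peaks_per_spectrum Number of uniform-random noise peaks
#'   added to every product-ion spectrum.
#' @param adduct_fraction_na Probability that a planted feature gets an
#'   `[M+Na]+` twin at exactly +21.9819.
#' @param snr_meanlog,snr_sdlog Log-normal signal-to-noise parameters.
#' @param seed Integer seed.
#' @return A list of class `synthetic_run_config`.
#' @export
synthetic_run_config <- function(parent_name, planted,
                                 decoys = NULL,
                                 mass_error_sd_ppm = 1,
                                 noise_peaks_per_spectrum = 5,
                                 adduct_fraction_na = 0.5,
                                 snr_meanlog = log(30), snr_sdlog = 0.3,
                                 seed = 1L) {
  stopifnot(mass_error_sd_ppm >= 0, noise_peaks_per_spectrum >= 0,
            adduct_fraction_na >= 0, adduct_fraction_na <= 1,
            all(planted$rt_min >= 0), all(planted$area >= 0))
  parent_compound(parent_name)  # validates
  needed <- c("chain_class", "site", "rt_min", "sample_id", "matrix", "area",
              "is_parent")
  missing_cols <- setdiff(needed, names(planted))
  if (length(missing_cols)) {
    stop("planted table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(decoys)) {
    decoys <- data.frame(mz = numeric(), rt_min = numeric(),
                         sample_id = character(), matrix = character(),
                         area = numeric(), stringsAsFactors = FALSE)
    decoys$fragments <- list()
  }
  structure(list(parent_name = parent_name, planted = planted, decoys = decoys,
                 mass_error_sd_ppm = mass_error_sd_ppm,
                 noise_peaks_per_spectrum = noise_peaks_per_spectrum,
                 adduct_fraction_na = adduct_fraction_na,
                 snr_meanlog = snr_meanlog, snr_sdlog = snr_sdlog,
                 seed = as.integer(seed)),
            class = "synthetic_run_config")
}

.scan_range <- c(50, 650)
.na_shift <- 21.9819

# Collision energy scales with precursor mass (25 eV around m/z 300,
# 32 eV around m/z 500).
.collision_energy <- function(precursor_mz) if (precursor_mz < 400) 25 else 32

.lookup_candidate <- function(candidates, chain_class) {
  hit <- candidates[candidates$chain_class == chain_class, , drop = FALSE]
  if (nrow(hit) == 0) {
    stop("no enumerated candidate with chain class '", chain_class, "'",
         call. = FALSE)
  }
  hit[1, , drop = FALSE]
}

#' Generate a synthetic LC-HRMS run
#'
#' Emulates a centroided feature table plus auto-MS/MS product-ion spectra
#' for a configured set of planted metabolites and decoys. Every planted
#' entry yields one feature with observed m/z = true m/z x (1 + e),
#' e ~ Normal(0, sd_ppm x 1e-6), a drawn log-normal signal-to-noise value,
#' with probability `adduct_fraction_na` an `[M+Na]+` twin at exactly
#' +21.9819 (no product-ion spectrum of its own), and one spectrum holding
#' the expected diagnostic fragments of the planted (chain, site) — each
#' with its own Gaussian ppm error — any curated metabolite-class ions, and
#' uniform-random noise peaks over m/z 50-650. Decoy entries yield features
#' (and spectra) whose fragment set matches no candidate.
#'
#' Draw order is fixed (per planted row: precursor error, snr, adduct coin,
#' fragment errors, noise m/z, noise intensities; then per decoy row), so a
#' given config + seed reproduces byte-identical files on any platform.
#'
#' @param config A [synthetic_run_config()].
#' @param out_dir Optional directory; if given, writes `features.csv` and
#'   `spectra.mgf` there.
#' @param candidates Optional pre-enumerated candidate table (defaults to
#'   [enumerate_candidates()] on the config's parent).
#' @return List with `features` (data.frame), `spectra` (list of
#'   [spectrum()]), `truth` (planted table with true and observed m/z), and
#'   the `config`; invisibly returns paths too when `out_dir` is given.
#' @export
generate_run <- function(config, out_dir = NULL, candidates = NULL) {
  stopifnot(inherits(config, "synthetic_run_config"))
  if (is.null(candidates)) {
    candidates <- enumerate_candidates(config$parent_name, max_steps = 3)
  }
  set.seed(config$seed)
  sd_rel <- config$mass_error_sd_ppm * 1e-6
  features <- list()
  spectra <- list()
  truth <- list()

  for (i in seq_len(nrow(config$planted))) {
    row <- config$planted[i, ]
    cand <- .lookup_candidate(candidates, row$chain_class)
    true_mz <- cand$`mz_[M+H]+`
    eps <- stats::rnorm(1, 0, sd_rel)
    obs_mz <- true_mz * (1 + eps)
    snr <- stats::rlnorm(1, config$snr_meanlog, config$snr_sdlog)
    na_coin <- stats::runif(1)

    features[[length(features) + 1L]] <- data.frame(
      sample_id = row$sample_id, matrix = row$matrix, rt_min = row$rt_min,
      mz = obs_mz, area = row$area, snr = snr, stringsAsFactors = FALSE
    )
    if (na_coin < config$adduct_fraction_na) {
      features[[length(features) + 1L]] <- data.frame(
        sample_id = row$sample_id, matrix = row$matrix, rt_min = row$rt_min,
        mz = obs_mz + .na_shift, area = row$area * 0.2, snr = snr,
        stringsAsFactors = FALSE
      )
    }

    frag <- expected_fragments(cand, row$site)
    extra <- inferred_class_ions(config$parent_name, row$chain_class)
    frag_mz <- c(frag$mz, extra$mz)
    frag_int <- 100 * 0.8^(seq_along(frag_mz) - 1)
    frag_eps <- stats::rnorm(length(frag_mz), 0, sd_rel)
    noise_mz <- stats::runif(config$noise_peaks_per_spectrum,
                             .scan_range[1], .scan_range[2])
    noise_int <- stats::runif(config$noise_peaks_per_spectrum, 0.5, 5)
    spectra[[length(spectra) + 1L]] <- spectrum(
      precursor_mz = obs_mz, rt_min = row$rt_min,
      peaks = cbind(c(frag_mz * (1 + frag_eps), noise_mz),
                    c(frag_int, noise_int)),
      collision_energy = .collision_energy(obs_mz),
      title = sprintf("planted|%s|%s|%s", row$sample_id,
                      cand$candidate_key, row$site)
    )
    truth[[length(truth) + 1L]] <- data.frame(
      candidate_key = cand$candidate_key, chain_class = row$chain_class,
      site = row$site, sample_id = row$sample_id, matrix = row$matrix,
      rt_min = row$rt_min, true_mz = true_mz, observed_mz = obs_mz,
      area = row$area, is_parent = row$is_parent, stringsAsFactors = FALSE
    )
  }

  for (i in seq_len(nrow(config$decoys))) {
    d <- config$decoys[i, ]
    snr <- stats::rlnorm(1, config$snr_meanlog, config$snr_sdlog)
    features[[length(features) + 1L]] <- data.frame(
      sample_id = d$sample_id, matrix = d$matrix, rt_min = d$rt_min,
      mz = d$mz, area = d$area, snr = snr, stringsAsFactors = FALSE
    )
    frag_mz <- d$fragments[[1]]
    frag_int <- 100 * 0.8^(seq_along(frag_mz) - 1)
    noise_mz <- stats::runif(config$noise_peaks_per_spectrum,
                             .scan_range[1], .scan_range[2])
    noise_int <- stats::runif(config$noise_peaks_per_spectrum, 0.5, 5)
    spectra[[length(spectra) + 1L]] <- spectrum(
      precursor_mz = d$mz, rt_min = d$rt_min,
      peaks = cbind(c(frag_mz, noise_mz), c(frag_int, noise_int)),
      collision_energy = .collision_energy(d$mz),
      title = sprintf("decoy|%s|%.4f", d$sample_id, d$mz)
    )
  }

  feat_df <- do.call(rbind, features)
  rownames(feat_df) <- NULL
  feat_df <- validate_features(feat_df)
  out <- list(features = feat_df, spectra = spectra,
              truth = do.call(rbind, truth), config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(feat_df, file.path(out_dir, "features.csv"))
    write_spectra_mgf(spectra, file.path(out_dir, "spectra.mgf"))
    out$paths <- c(features = file.path(out_dir, "features.csv"),
                   spectra = file.path(out_dir, "spectra.mgf"))
  }
  out
}

# Table-derived panel rows: printed retention times, MAR-proportional areas.
.admb_panel_rows <- function() {
  rows <- rbind(
    data.frame(chain_class = "hydroxylation", site = "S", rt_min = 7.02,
               urine = 78.37, phlm = 54.03),
    data.frame(chain_class = "hydroxylation", site = "S", rt_min = 7.96,
               urine = 100.00, phlm = 100.00),
    data.frame(chain_class = "dihydroxylation", site = "S", rt_min = 4.34,
               urine = 57.96, phlm = 13.59),
    data.frame(chain_class = "cleavage_3tms_terminal_hydroxylation", site = "S",
               rt_min = 2.91, urine = 48.39, phlm = 26.65),
    data.frame(chain_class = "carboxylic_acid_formation+cleavage_3tms_terminal_hydroxylation",
               site = "S", rt_min = 2.97, urine = 53.27, phlm = 0.99),
    data.frame(chain_class = "demethylation+dihydroxylation", site = "S",
               rt_min = 3.63, urine = 41.73, phlm = 1.46),
    data.frame(chain_class = "", site = "unknown", rt_min = 13.10,
               urine = NA, phlm = 200)  # parent: not detected in urine
  )
  rows
}

.cumyl_panel_rows <- function() {
  rbind(
    data.frame(chain_class = "hydroxylation", site = "S", rt_min = 13.18,
               urine = 100.00, phlm = 74.36),
    data.frame(chain_class = "demethylation+hydroxylation", site = "S",
               rt_min = 11.44, urine = 1.78, phlm = 22.26),
    data.frame(chain_class = "cleavage_3tms_terminal_hydroxylation", site = "S",
               rt_min = 6.92, urine = 75.48, phlm = 100.0),
    data.frame(chain_class = "cleavage_3tms_terminal_hydroxylation+ketone_aldehyde_formation",
               site = "S", rt_min = 8.17, urine = NA, phlm = 34.14),
    data.frame(chain_class = "carboxylic_acid_formation+cleavage_3tms_terminal_hydroxylation",
               site = "S", rt_min = 6.87, urine = 70.66, phlm = 32.83),
    data.frame(chain_class = "demethylation+dihydroxylation", site = "S",
               rt_min = 7.66, urine = 16.74, phlm = 19.25),
    data.frame(chain_class = "", site = "unknown", rt_min = 16.02,
               urine = NA, phlm = 200)
  )
}

.panel_planted <- function(rows) {
  out <- list()
  for (m in c("urine", "phlm")) {
    col <- rows[[m]]
    keep <- !is.na(col)
    if (!any(keep)) next
    out[[m]] <- data.frame(
      chain_class = rows$chain_class[keep], site = rows$site[keep],
      rt_min = rows$rt_min[keep],
      sample_id = paste0(m, "_1"),
      matrix = if (m == "urine") "urine" else "pHLM",
      area = col[keep],
      is_parent = rows$chain_class[keep] == "",
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

# Fragment m/z of the isobaric N-3-hydroxybutyl interference (hydroxybutyl
# indazole acylium at nominal 217 differs from the carboxylic acid fragment
# by ~0.07 Da, far outside the 10 ppm tolerance).
.decoy_fragments <- c(217.1285, 163.1230, 132.0808)

#' Preset synthetic-run configurations
#'
#' * `admb_panel` / `cumyl_panel`: plant the tabulated phase I metabolite
#'   panel of the respective parent at the printed retention times, with
#'   areas equal to the printed MAR percentages, in one urine and one pHLM
#'   sample (entries printed "not detected" in a matrix are not planted
#'   there; the parent is planted in vitro only).
#' * `isobar_case`: the N-propionic-acid metabolite plus an isobaric decoy
#'   at the same m/z eluting 3.5 min later with a non-matching fragment set.
#' * `noise_stress`: the admb_panel with dense noise peaks, a wide
#'   signal-to-noise distribution (so the S/N > 3 filter is exercised both
#'   ways), and 7.5-ppm off-target decoys.
#'
#' @param name Preset name.
#' @param seed Integer seed stored in the config.
#' @return A [synthetic_run_config()].
#' @examples
#' cfg <- preset("admb_panel", seed = 7)
#' run <- generate_run(cfg)
#' nrow(run$features)
#' @export
preset <- function(name = c("admb_panel", "cumyl_panel", "isobar_case",
                            "noise_stress"),
                   seed = 1L) {
  name <- match.arg(name)
  if (name == "admb_panel") {
    synthetic_run_config("ADMB-3TMS-PrINACA", .panel_planted(.admb_panel_rows()),
                         seed = seed)
  } else if (name == "cumyl_panel") {
    synthetic_run_config("Cumyl-3TMS-PrINACA", .panel_planted(.cumyl_panel_rows()),
                         seed = seed)
  } else if (name == "isobar_case") {
    planted <- data.frame(
      chain_class = "carboxylic_acid_formation+cleavage_3tms_terminal_hydroxylation",
      site = "S", rt_min = 2.97, sample_id = "urine_1", matrix = "urine",
      area = 53.27, is_parent = FALSE, stringsAsFactors = FALSE
    )
    decoys <- data.frame(mz = round_mz(mz("C17H22N4O4")), rt_min = 6.5,
                         sample_id = "urine_1", matrix = "urine", area = 80,
                         stringsAsFactors = FALSE)
    decoys$fragments <- list(.decoy_fragments)
    synthetic_run_config("ADMB-3TMS-PrINACA", planted, decoys = decoys,
                         adduct_fraction_na = 0, seed = seed)
  } else {
    planted <- .panel_planted(.admb_panel_rows())
    targets <- c("C20H32N4O3Si", "C17H22N4O4")
    decoys <- data.frame(
      mz = vapply(targets, function(f) mz(f) * (1 + 7.5e-6), numeric(1)),
      rt_min = c(9.5, 5.5), sample_id = "urine_1", matrix = "urine",
      area = c(60, 40), stringsAsFactors = FALSE
    )
    decoys$fragments <- list(.decoy_fragments, .decoy_fragments)
    cfg <- synthetic_run_config("ADMB-3TMS-PrINACA", planted, decoys = decoys,
                                noise_peaks_per_spectrum = 30,
                                snr_meanlog = log(10), snr_sdlog = 1,
                                seed = seed)
    cfg
  }
}

#' Recovery summary for a synthetic run
#'
#' Screens a generated run with the standard criteria and reports how many
#' planted metabolites were recovered (precursor match accepted and at
#' least `min_matches` diagnostic fragments found) and how many decoy
#' features were fully accepted. Used for parameter-recovery studies across
#' many seeds.
#'
#' @param run Output of [generate_run()].
#' @param candidates Optional pre-enumerated candidate table (amortizes
#'   enumeration across seeds).
#' @param config A [screening_config()].
#' @param cache Environment used to memoize expected-fragment sets across
#'   repeated calls (see [recovery_study()]).
#' @return List with `n_planted`, `n_recovered`, `n_decoys`,
#'   `n_decoys_accepted`.
#' @export
recovery_summary <- function(run, candidates = NULL,
                             config = screening_config(),
                             cache = new.env(parent = emptyenv())) {
  cfg <- config
  if (is.null(candidates)) {
    candidates <- enumerate_candidates(run$config$parent_name,
                                       max_steps = cfg$max_steps, phases = "I",
                                       adducts = "[M+H]+")
  }
  expected_union_cached <- function(cand) {
    key <- cand$candidate_key
    if (is.null(cache[[key]])) cache[[key]] <- .expected_union(cand)
    cache[[key]]
  }
  inclusion <- build_inclusion_list(candidates, adducts = "[M+H]+",
                                    ppm_window = cfg$ppm_tol)
  matches <- match_precursors(run$features, inclusion, ppm_tol = cfg$ppm_tol,
                              snr_min = cfg$snr_min)
  full_accept <- function(feature_mz, feature_rt, target_mz) {
    hit <- matches[matches$accepted &
                     abs(matches$mz - feature_mz) < 1e-9 &
                     abs(matches$rt_min - feature_rt) < 1e-9 &
                     abs(matches$target_mz - target_mz) < 5e-4, , drop = FALSE]
    if (nrow(hit) == 0) return(FALSE)
    sp <- .nearest_spectrum(run$spectra, feature_mz, feature_rt,
                            cfg$spectrum_pairing_ppm, cfg$spectrum_pairing_rt)
    if (is.null(sp)) return(FALSE)
    for (k in seq_len(nrow(hit))) {
      cand <- candidates[candidates$candidate_key == hit$candidate_key[k], ,
                         drop = FALSE]
      row <- match_fragments(hit[k, , drop = FALSE], sp,
                             expected_union_cached(cand),
                             tol_ppm = cfg$fragment_tol_ppm,
                             min_matches = cfg$min_matches)
      if (row$accepted) return(TRUE)
    }
    FALSE
  }
  truth <- run$truth
  recovered <- vapply(seq_len(nrow(truth)), function(i) {
    full_accept(truth$observed_mz[i], truth$rt_min[i], truth$true_mz[i])
  }, logical(1))
  decoys <- run$config$decoys
  decoy_accepted <- if (nrow(decoys)) {
    vapply(seq_len(nrow(decoys)), function(i) {
      hit <- matches[matches$accepted &
                       abs(matches$mz - decoys$mz[i]) < 1e-9 &
                       abs(matches$rt_min - decoys$rt_min[i]) < 1e-9, ,
                     drop = FALSE]
      if (nrow(hit) == 0) return(FALSE)
      sp <- .nearest_spectrum(run$spectra, decoys$mz[i], decoys$rt_min[i],
                              cfg$spectrum_pairing_ppm, cfg$spectrum_pairing_rt)
      for (k in seq_len(nrow(hit))) {
        cand <- candidates[candidates$candidate_key == hit$candidate_key[k], ,
                           drop = FALSE]
        row <- match_fragments(hit[k, , drop = FALSE], sp,
                               expected_union_cached(cand),
                               tol_ppm = cfg$fragment_tol_ppm,
                               min_matches = cfg$min_matches)
        if (row$accepted) return(TRUE)
      }
      FALSE
    }, logical(1))
  } else {
    logical(0)
  }
  list(n_planted = nrow(truth), n_recovered = sum(recovered),
       n_decoys = nrow(decoys), n_decoys_accepted = sum(decoy_accepted))
}

#' Multi-seed parameter-recovery study
#'
#' Generates a preset synthetic run for each seed and screens it with the
#' standard criteria, accumulating how many planted metabolites were
#' recovered and how many decoys were fully accepted. Candidate enumeration
#' and expected-fragment sets are computed once and shared across seeds.
#'
#' @param preset_name A [preset()] name.
#' @param seeds Integer vector of seeds.
#' @param mass_error_sd_ppm Override of the preset's mass-error model
#'   (`NULL` keeps the preset default).
#' @param config A [screening_config()].
#' @return List with totals `n_planted`, `n_recovered`, `n_decoys`,
#'   `n_decoys_accepted` and the derived `recovery_rate` and
#'   `decoy_acceptance_rate` (NA when the preset has no decoys).
#' @export
recovery_study <- function(preset_name, seeds = 1:100,
                           mass_error_sd_ppm = NULL,
                           config = screening_config()) {
  first <- preset(preset_name, seed = seeds[1])
  candidates <- enumerate_candidates(first$parent_name,
                                     max_steps = config$max_steps,
                                     phases = "I", adducts = "[M+H]+")
  cache <- new.env(parent = emptyenv())
  totals <- c(n_planted = 0, n_recovered = 0, n_decoys = 0,
              n_decoys_accepted = 0)
  for (s in seeds) {
    cfg <- preset(preset_name, seed = s)
    if (!is.null(mass_error_sd_ppm)) cfg$mass_error_sd_ppm <- mass_error_sd_ppm
    run <- generate_run(cfg, candidates = candidates)
    rs <- recovery_summary(run, candidates, config, cache = cache)
    totals <- totals + c(rs$n_planted, rs$n_recovered, rs$n_decoys,
                         rs$n_decoys_accepted)
  }
  out <- as.list(totals)
  out$recovery_rate <- out$n_recovered / out$n_planted
  out$decoy_acceptance_rate <-
    if (out$n_decoys > 0) out$n_decoys_accepted / out$n_decoys else NA_real_
  out
}
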