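#' Match features against an inclusion list (precursor stage)
#'
#' Pairs every feature with every inclusion-list row whose target m/z lies
#' within a reporting window, computes the signed precursor ppm error, and
#' applies the identification criteria: precursor mass error strictly below
#' `ppm_tol` and signal-to-noise strictly above `snr_min`. Pairs failing a
#' criterion are kept with `accepted = FALSE` and a `rejection_reason`
#' (`ppm_exceeded` takes precedence over `snr_low`), so every rejection is
#' loggable. Fragment evidence is evaluated separately by
#' [match_fragments()].
#'
#' @param features Validated feature table (see [validate_features()]).
#' @param inclusion_list Inclusion list from [build_inclusion_list()].
#' @param ppm_tol Precursor tolerance in ppm (match requires |ppm| < ppm_tol).
#' @param snr_min Signal-to-noise threshold (match requires snr > snr_min).
#' @param report_window_ppm Pairs beyond `ppm_tol` but within this window are
#'   reported as rejected rather than dropped silently.
#' @return Data.frame of precursor matches in deterministic order (feature
#'   row, then target m/z): feature columns plus `feature_id`,
#'   `candidate_key`, `adduct`, `target_mz`, `ppm_error_precursor`,
#'   `accepted`, `rejection_reason`.
#' @export
match_precursors <- function(features, inclusion_list, ppm_tol = 5,
                             snr_min = 3, report_window_ppm = 20) {
  features <- validate_features(features)
  if (is.null(inclusion_list) || nrow(inclusion_list) == 0) {
    stop("inclusion list is empty", call. = FALSE)
  }
  stopifnot(ppm_tol > 0, snr_min >= 0, report_window_ppm >= ppm_tol)
  out <- list()
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    ppm <- ppm_error(f$mz, inclusion_list$mz)
    hit <- which(abs(ppm) <= report_window_ppm)
    for (j in hit) {
      p <- ppm[j]
      reason <- if (abs(p) >= ppm_tol) {
        "ppm_exceeded"
      } else if (f$snr <= snr_min) {
        "snr_low"
      } else {
        "none"
      }
      out[[length(out) + 1L]] <- data.frame(
        feature_id = i,
        sample_id = f$sample_id, matrix = f$matrix,
        rt_min = f$rt_min, mz = f$mz, area = f$area, snr = f$snr,
        candidate_key = inclusion_list$candidate_key[j],
        adduct = inclusion_list$adduct[j],
        target_mz = inclusion_list$mz[j],
        ppm_error_precursor = p,
        accepted = reason == "none",
        rejection_reason = reason,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(
      feature_id = integer(), sample_id = character(), matrix = character(),
      rt_min = numeric(), mz = numeric(), area = numeric(), snr = numeric(),
      candidate_key = character(), adduct = character(), target_mz = numeric(),
      ppm_error_precursor = numeric(), accepted = logical(),
      rejection_reason = character(), stringsAsFactors = FALSE
    ))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$feature_id, res$target_mz, res$candidate_key), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Match expected product ions in a spectrum (fragment stage)
#'
#' Matches each expected diagnostic fragment to the nearest spectrum peak
#' within the fragment mass tolerance (inclusive, |ppm| <= `tol_ppm`). The
#' match is accepted iff the precursor stage passed and at least
#' `min_matches` fragments are found; otherwise the rejection reason is
#' `insufficient_fragments`.
#'
#' @param match One row of [match_precursors()] output.
#' @param spec A [spectrum()] whose precursor corresponds to the match.
#' @param expected Data.frame of expected fragments with columns `name`
#'   and `mz` (see [expected_fragments()]).
#' @param tol_ppm Fragment tolerance in ppm (inclusive).
#' @param min_matches Minimum number of matched diagnostic fragments for an
#'   identification.
#' @return The match row with columns `n_fragments_matched`, updated
#'   `accepted`/`rejection_reason`, and a `matched_fragments` list column
#'   holding a data.frame (`name`, `expected_mz`, `observed_mz`, `ppm`).
#' @export
match_fragments <- function(match, spec, expected, tol_ppm = 10, min_matches = 1) {
  stopifnot(nrow(match) == 1, tol_ppm > 0, min_matches >= 0)
  matched <- data.frame(name = character(), expected_mz = numeric(),
                        observed_mz = numeric(), ppm = numeric(),
                        stringsAsFactors = FALSE)
  if (!is.null(spec) && !is.null(expected) && nrow(expected) > 0 &&
      nrow(spec$peaks) > 0) {
    for (i in seq_len(nrow(expected))) {
      exp_mz <- expected$mz[i]
      ppm <- ppm_error(spec$peaks[, "mz"], exp_mz)
      j <- which.min(abs(ppm))
      if (abs(ppm[j]) <= tol_ppm) {
        matched <- rbind(matched, data.frame(
          name = expected$name[i], expected_mz = exp_mz,
          observed_mz = spec$peaks[j, "mz"], ppm = ppm[j],
          stringsAsFactors = FALSE
        ))
      }
    }
  }
  match$n_fragments_matched <- nrow(matched)
  if (match$accepted && nrow(matched) < min_matches) {
    match$accepted <- FALSE
    match$rejection_reason <- "insufficient_fragments"
  }
  match$matched_fragments <- list(matched)
  match
}

#' Discriminate isobaric matches by retention time
#'
#' Matches sharing a target m/z are separated into distinct identifications
#' when their retention times differ by more than `rt_window` minutes;
#' co-eluting duplicates (same target, |delta rt| <= window, same sample)
#' are collapsed to the best match: smallest |precursor ppm|, then the
#' shortest transformation chain, then the lowest candidate mass (requires
#' `candidates`), then the candidate key.
#'
#' @param matches Data.frame of matches (any stage).
#' @param rt_window Co-elution window in minutes (> 0).
#' @param candidates Optional [enumerate_candidates()] output used for the
#'   chain-length/mass tie-break.
#' @return `matches` with an `identification_id` column, duplicates removed.
#' @export
discriminate_isobars <- function(matches, rt_window = 0.2, candidates = NULL) {
  stopifnot(rt_window > 0)
  if (nrow(matches) == 0) {
    matches$identification_id <- character(0)
    return(matches)
  }
  n_steps <- mass <- rep(NA_real_, nrow(matches))
  if (!is.null(candidates)) {
    idx <- match(matches$candidate_key, candidates$candidate_key)
    n_steps <- candidates$n_steps[idx]
    mass <- candidates$mass[idx]
  }
  key <- sprintf("%.4f|%s", matches$target_mz, matches$sample_id)
  out <- list()
  for (g in split(seq_len(nrow(matches)), key)) {
    g <- g[order(matches$rt_min[g])]
    # cluster by rt: a gap > rt_window starts a new identification
    rt <- matches$rt_min[g]
    cluster <- cumsum(c(TRUE, diff(rt) > rt_window))
    for (cl in split(g, cluster)) {
      ord <- order(abs(matches$ppm_error_precursor[cl]), n_steps[cl],
                   mass[cl], matches$candidate_key[cl])
      best <- cl[ord[1]]
      row <- matches[best, , drop = FALSE]
      row$identification_id <- sprintf("%s@%.2f", sprintf("%.4f", row$target_mz),
                                       stats::median(matches$rt_min[cl]))
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$target_mz, res$rt_min, res$sample_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.roman_label <- function(prefix, i) paste(prefix, as.character(utils::as.roman(i)))

#' Assign retention-time-ordered metabolite identifiers
#'
#' Metabolites are labelled by biotransformation stage (from the parent's
#' stage registry, which maps a canonical chain class to a stage number) and
#' ordered by retention time within a stage: singleton stages get the bare
#' number (`"A8"`), stages with several isomers get rt-ascending suffixes
#' (`"A1.1"`, `"A1.2"`, ...). Phase II conjugates get rt-ordered roman
#' numerals (`"A I"`, `"A II"`, ...). Stage 0 is the parent.
#'
#' @param accepted Data.frame of accepted identifications with columns
#'   `candidate_key`, `chain_class`, `rt_min`, and `phase`.
#' @param stage_registry Named integer vector mapping chain class to stage
#'   number (see [parent_compound()]).
#' @param prefix Metabolite-ID prefix letter (e.g. `"A"`).
#' @param rt_window Observations of one candidate within this window
#'   (minutes) are one metabolite; wider gaps are retention-time isomers
#'   that get their own labels.
#' @return Data.frame `candidate_key`, `label`, `stage`, `rt_rank`, `rt_min`.
#' @export
assign_ids <- function(accepted, stage_registry, prefix, rt_window = 0.2) {
  if (nrow(accepted) == 0) {
    return(data.frame(candidate_key = character(), label = character(),
                      stage = integer(), rt_rank = integer(),
                      rt_min = numeric(), stringsAsFactors = FALSE))
  }
  # One entity per (candidate, rt cluster): a candidate observed in several
  # samples at one rt is a single metabolite; rt-separated observations of
  # one composition+chain are isomers and are labelled separately.
  agg <- do.call(rbind, lapply(
    split(accepted,
          paste(accepted$candidate_key, accepted$chain_class, accepted$phase,
                sep = "\r")),
    function(grp) {
      grp <- grp[order(grp$rt_min), , drop = FALSE]
      cl <- cumsum(c(TRUE, diff(grp$rt_min) > rt_window))
      do.call(rbind, lapply(split(grp, cl), function(g) {
        data.frame(candidate_key = g$candidate_key[1],
                   chain_class = g$chain_class[1], phase = g$phase[1],
                   rt_min = stats::median(g$rt_min), stringsAsFactors = FALSE)
      }))
    }))
  rownames(agg) <- NULL
  unknown <- setdiff(agg$chain_class[agg$phase != "II"], names(stage_registry))
  if (length(unknown)) {
    stop("chain class(es) missing from the stage registry: ",
         paste(unknown, collapse = "; "), call. = FALSE)
  }
  phase1 <- agg[agg$phase != "II", , drop = FALSE]
  phase2 <- agg[agg$phase == "II", , drop = FALSE]
  out <- list()
  if (nrow(phase1)) {
    # match() rather than name indexing: the parent's chain class is ""
    phase1$stage <- unname(stage_registry[match(phase1$chain_class,
                                                names(stage_registry))])
    for (st in unique(phase1$stage)) {
      grp <- phase1[phase1$stage == st, , drop = FALSE]
      grp <- grp[order(grp$rt_min, grp$candidate_key), , drop = FALSE]
      for (k in seq_len(nrow(grp))) {
        label <- if (nrow(grp) == 1) {
          paste0(prefix, st)
        } else {
          paste0(prefix, st, ".", k)
        }
        out[[length(out) + 1L]] <- data.frame(
          candidate_key = grp$candidate_key[k], label = label,
          stage = st, rt_rank = k, rt_min = grp$rt_min[k],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (nrow(phase2)) {
    phase2 <- phase2[order(phase2$rt_min, phase2$candidate_key), , drop = FALSE]
    for (k in seq_len(nrow(phase2))) {
      out[[length(out) + 1L]] <- data.frame(
        candidate_key = phase2$candidate_key[k],
        label = .roman_label(prefix, k),
        stage = NA_integer_, rt_rank = k, rt_min = phase2$rt_min[k],
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(is.na(res$stage), res$stage, res$rt_rank), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Mean area ratio (MAR) table
#'
#' Normalizes, within each sample, every metabolite's chromatographic peak
#' area to the most abundant metabolite of that sample (= 100), after
#' excluding the parent compound; the per-matrix MAR is the arithmetic mean
#' of these per-sample ratios across the samples of a matrix (over the
#' samples in which the metabolite was detected). Peak areas are arbitrary
#' units, so MAR is invariant under uniform area scaling.
#'
#' @param accepted Data.frame with columns `label`, `sample_id`, `matrix`,
#'   `area`, and logical `is_parent`.
#' @param exclude_parent Drop parent rows before normalizing (default TRUE).
#' @return Data.frame `label`, `matrix`, `mar` (percent, max 100 per
#'   matrix/sample).
#' @export
compute_mar <- function(accepted, exclude_parent = TRUE) {
  df <- accepted
  if (exclude_parent) df <- df[!df$is_parent, , drop = FALSE]
  if (nrow(df) == 0) {
    stop("no metabolites left for MAR computation after excluding the parent",
         call. = FALSE)
  }
  parts <- split(df, paste(df$matrix, df$sample_id, sep = "\r"))
  ratios <- do.call(rbind, lapply(parts, function(p) {
    if (nrow(p) == 0) return(NULL)
    p$ratio <- p$area / max(p$area) * 100
    p[, c("label", "matrix", "ratio")]
  }))
  agg <- stats::aggregate(ratio ~ label + matrix, data = ratios, FUN = mean)
  names(agg)[names(agg) == "ratio"] <- "mar"
  agg <- agg[order(agg$matrix, -agg$mar, agg$label), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Flag biomarker specificity
#'
#' Metabolite labels listed in the cross-reactivity registry (biomarkers
#' also produced by structurally related compounds) are flagged
#' `nonspecific`; all others are `specific`.
#'
#' @param labels Character vector of metabolite labels.
#' @param cross_reactivity Named list: related compound -> shared labels
#'   (see [parent_compound()]); an empty registry flags everything specific.
#' @return Named character vector label -> `"specific"`/`"nonspecific"`.
#' @export
flag_specificity <- function(labels, cross_reactivity = list()) {
  shared <- unique(unlist(cross_reactivity, use.names = FALSE))
  stats::setNames(
    ifelse(labels %in% shared, "nonspecific", "specific"),
    labels
  )
}
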