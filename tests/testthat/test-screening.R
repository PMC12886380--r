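inclusion_a10 <- function() {
  cands <- enumerate_candidates("ADMB-3TMS-PrINACA", max_steps = 3,
                                phases = "I", adducts = "[M+H]+")
  build_inclusion_list(cands, adducts = "[M+H]+", ppm_window = 5)
}

feature_row <- function(mz, snr = 10, rt = 2.97) {
  data.frame(sample_id = "s1", matrix = "urine", rt_min = rt, mz = mz,
             area = 100, snr = snr, stringsAsFactors = FALSE)
}

test_that("precursor matching applies the <5 ppm and S/N>3 criteria", {
  il <- inclusion_a10()
  m <- match_precursors(feature_row(347.1716, snr = 10), il)
  hit <- m[abs(m$target_mz - 347.1714) < 0.01, ]
  expect_true(any(hit$accepted))
  expect_equal(hit$ppm_error_precursor[hit$accepted][1], 0.6, tolerance = 0.1)

  low_snr <- match_precursors(feature_row(347.1714, snr = 2.5), il)
  hit <- low_snr[abs(low_snr$target_mz - 347.1714) < 0.01, ]
  expect_false(any(hit$accepted))
  expect_true(all(hit$rejection_reason == "snr_low"))

  off <- match_precursors(feature_row(347.1740), il)
  hit <- off[abs(off$target_mz - 347.1714) < 0.01, ]
  expect_false(any(hit$accepted))
  expect_true(all(hit$rejection_reason == "ppm_exceeded"))
  expect_equal(hit$ppm_error_precursor[1], 7.5, tolerance = 0.2)

  expect_error(match_precursors(feature_row(347.1714), il[0, ]), "empty")
})

test_that("boundary semantics: 5.5 ppm and S/N 2.9 are rejected correctly", {
  il <- inclusion_a10()
  mz_55 <- 347.1714 * (1 + 5.5e-6)
  m <- match_precursors(feature_row(mz_55, snr = 10), il)
  hit <- m[abs(m$target_mz - 347.1714) < 0.01, ]
  expect_identical(unique(hit$rejection_reason), "ppm_exceeded")
  m2 <- match_precursors(feature_row(347.1714, snr = 2.9), il)
  hit2 <- m2[abs(m2$target_mz - 347.1714) < 0.01, ]
  expect_identical(unique(hit2$rejection_reason), "snr_low")
})

test_that("acceptance is monotone when the ppm tolerance widens", {
  il <- inclusion_a10()
  feats <- do.call(rbind, lapply(c(347.1714, 347.1721, 347.1730, 347.1745),
                                 feature_row))
  narrow <- match_precursors(feats, il, ppm_tol = 3)
  wide <- match_precursors(feats, il, ppm_tol = 8)
  key <- function(m) paste(m$feature_id, m$candidate_key)
  expect_true(all(key(narrow)[narrow$accepted] %in% key(wide)[wide$accepted]))
})

test_that("precursor matching agrees with an exhaustive all-pairs filter", {
  il <- inclusion_a10()
  il <- il[seq_len(min(20, nrow(il))), ]
  class(il) <- c("inclusion_list", "data.frame")
  set.seed(99)
  feats <- do.call(rbind, lapply(seq_len(20), function(i) {
    base <- sample(il$mz, 1)
    feature_row(base * (1 + stats::runif(1, -12e-6, 12e-6)),
                snr = stats::runif(1, 1, 20), rt = stats::runif(1, 1, 15))
  }))
  got <- match_precursors(feats, il)
  got_acc <- got[got$accepted, c("feature_id", "candidate_key")]
  # brute force: every (feature, row) pair, strict criteria
  brute <- list()
  for (i in seq_len(nrow(feats))) {
    for (j in seq_len(nrow(il))) {
      ppm <- 1e6 * (feats$mz[i] - il$mz[j]) / il$mz[j]
      if (abs(ppm) < 5 && feats$snr[i] > 3) {
        brute[[length(brute) + 1L]] <- data.frame(
          feature_id = i, candidate_key = il$candidate_key[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  brute <- if (length(brute)) do.call(rbind, brute) else
    data.frame(feature_id = integer(), candidate_key = character())
  expect_setequal(paste(got_acc$feature_id, got_acc$candidate_key),
                  paste(brute$feature_id, brute$candidate_key))
})

test_that("fragment matching honours the inclusive 10 ppm tolerance", {
  il <- inclusion_a10()
  m <- match_precursors(feature_row(347.1714), il)
  m <- m[abs(m$target_mz - 347.1714) < 0.01, ][1, ]
  expected <- data.frame(name = c("acid_ion", "acylium"),
                         mz = c(217.0608, 145.0396), stringsAsFactors = FALSE)
  good <- spectrum(347.1714, 2.97, cbind(c(217.0608, 145.0396), c(100, 50)))
  r <- match_fragments(m, good, expected)
  expect_true(r$accepted)
  expect_identical(r$n_fragments_matched, 2L)

  empty <- spectrum(347.1714, 2.97, matrix(numeric(), ncol = 2))
  r2 <- match_fragments(m, empty, expected)
  expect_false(r2$accepted)
  expect_identical(r2$rejection_reason, "insufficient_fragments")

  # a peak ~10.1 ppm off is not matched
  off <- spectrum(347.1714, 2.97, cbind(217.0630, 100))
  r3 <- match_fragments(m, off, expected)
  expect_identical(r3$n_fragments_matched, 0L)
})

test_that("isobars separate by retention time and co-elutions collapse", {
  il <- inclusion_a10()
  two <- rbind(feature_row(347.1715, rt = 2.97), feature_row(347.1713, rt = 3.60))
  m <- match_precursors(two, il)
  m <- m[abs(m$target_mz - 347.1714) < 0.01, ]
  sep <- discriminate_isobars(m, rt_window = 0.2)
  expect_identical(nrow(sep), 2L)

  dup <- rbind(feature_row(347.1715, rt = 2.97), feature_row(347.1713, rt = 3.02))
  m2 <- match_precursors(dup, il)
  m2 <- m2[abs(m2$target_mz - 347.1714) < 0.01, ]
  col <- discriminate_isobars(m2, rt_window = 0.2)
  expect_identical(nrow(col), 1L)
  # the better (smaller |ppm|) duplicate wins
  expect_equal(col$mz, 347.1713, tolerance = 1e-6)

  empty <- m2[0, ]
  expect_identical(nrow(discriminate_isobars(empty, 0.2)), 0L)
})

test_that("metabolite IDs are stage-grouped and rt-ordered", {
  reg <- admb()$stage_registry
  acc <- data.frame(
    candidate_key = c("k_oh", "k_oh", "k_acid", "k_parent"),
    chain_class = c("hydroxylation", "hydroxylation",
                    "carboxylic_acid_formation+cleavage_3tms_terminal_hydroxylation",
                    ""),
    phase = "I",
    rt_min = c(7.96, 7.02, 2.97, 13.10),
    stringsAsFactors = FALSE
  )
  ids <- assign_ids(acc, reg, "A")
  expect_identical(ids$label[ids$rt_min == 7.02], "A1.1")
  expect_identical(ids$label[ids$rt_min == 7.96], "A1.2")
  expect_identical(ids$label[ids$rt_min == 2.97], "A10")  # singleton stage
  expect_identical(ids$label[ids$rt_min == 13.10], "A0")
  # stable under permutation of input order
  ids2 <- assign_ids(acc[c(3, 1, 4, 2), ], reg, "A")
  expect_identical(ids[order(ids$label), ], ids2[order(ids2$label), ])
  expect_error(assign_ids(transform(acc, chain_class = "made_up"), reg, "A"),
               "missing from the stage registry")
  expect_identical(nrow(assign_ids(acc[0, ], reg, "A")), 0L)
})

test_that("phase II conjugates get rt-ordered roman numerals", {
  acc <- data.frame(
    candidate_key = c("g1", "g2"),
    chain_class = c("hydroxylation+o_glucuronidation",
                    "o_glucuronidation+trihydroxylation"),
    phase = "II", rt_min = c(5.0, 3.2), stringsAsFactors = FALSE
  )
  ids <- assign_ids(acc, admb()$stage_registry, "A")
  expect_identical(ids$label, c("A I", "A II"))
  expect_identical(ids$candidate_key, c("g2", "g1"))  # earlier rt first
})

test_that("MAR normalizes per sample, excludes the parent, and averages", {
  one <- data.frame(
    label = c("x", "y", "z", "P"), sample_id = "s1", matrix = "urine",
    area = c(50, 100, 25, 500), is_parent = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  m <- compute_mar(one)
  expect_equal(m$mar[match(c("x", "y", "z"), m$label)], c(50, 100, 25))
  expect_false("P" %in% m$label)
  expect_equal(max(m$mar), 100.0)

  single <- compute_mar(one[2, ])
  expect_equal(single$mar, 100.0)

  two <- rbind(
    data.frame(label = c("x", "y"), sample_id = "s1", matrix = "urine",
               area = c(100, 50), is_parent = FALSE),
    data.frame(label = c("x", "y"), sample_id = "s2", matrix = "urine",
               area = c(200, 120), is_parent = FALSE)
  )
  m2 <- compute_mar(two)
  expect_equal(m2$mar[m2$label == "x"], 100.0)
  expect_equal(m2$mar[m2$label == "y"], 55.0)  # mean of 50 and 60

  # invariance under uniform area scaling
  scaled <- transform(two, area = area * 17.3)
  expect_equal(compute_mar(scaled)$mar, m2$mar, tolerance = 1e-12)

  expect_error(compute_mar(one[4, , drop = FALSE]), "no metabolites")
})

test_that("specificity flags follow the cross-reactivity registry", {
  reg <- cumyl()$cross_reactivity
  flags <- flag_specificity(c("C6", "C8", "C1.2"), reg)
  expect_identical(unname(flags[c("C6", "C8")]),
                   c("nonspecific", "nonspecific"))
  expect_identical(unname(flags[["C1.2"]]), "specific")
  expect_identical(unname(flag_specificity(c("C6"), list())), "specific")
})
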