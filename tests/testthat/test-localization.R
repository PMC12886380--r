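test_that("side-chain hydroxylation is called from shifted/unshifted ions", {
  cands <- enumerate_candidates("Cumyl-3TMS-PrINACA", max_steps = 1)
  hydroxy <- cands[cands$chain_class == "hydroxylation", ][1, ]
  # shifted 275.1210 with unaltered 145.0396 and 119.0855 -> side chain
  sp <- spectrum(410.2258, 13.2,
                 cbind(c(275.1210, 119.0855, 145.0396), c(100, 80, 60)))
  call <- infer_site(hydroxy, sp)
  expect_identical(call$site, "S")
  ev <- stats::setNames(call$evidence$status, call$evidence$fragment)
  expect_identical(unname(ev["indazolyl_acylium_3tms"]), "shifted")
  expect_identical(unname(ev["cumyl"]), "unshifted")
})

test_that("a hydroxylated cumyl ion (135.0804) places the head group", {
  cands <- enumerate_candidates("Cumyl-3TMS-PrINACA", max_steps = 1)
  hydroxy <- cands[cands$chain_class == "hydroxylation", ][1, ]
  call <- infer_site(hydroxy, spectrum(410.2258, 12, cbind(135.0804, 100)))
  expect_identical(call$site, "H")
})

test_that("no fragment evidence gives undetermined, never an error", {
  cands <- enumerate_candidates("Cumyl-3TMS-PrINACA", max_steps = 1)
  hydroxy <- cands[cands$chain_class == "hydroxylation", ][1, ]
  expect_identical(
    infer_site(hydroxy, spectrum(410.2258, 12, matrix(numeric(), ncol = 2)))$site,
    "undetermined")
  expect_identical(infer_site(hydroxy, NULL)$site, "undetermined")
  # the parent (empty chain) has no site to infer
  parent_row <- enumerate_candidates("Cumyl-3TMS-PrINACA", max_steps = 0)[1, ]
  expect_identical(infer_site(parent_row, NULL)$site, "undetermined")
})

test_that("complete synthetic evidence round-trips every single-step site", {
  reg <- default_rule_registry()
  for (parent_name in parent_compound()) {
    cands <- enumerate_candidates(parent_name, max_steps = 1)
    for (i in seq_len(nrow(cands))) {
      chain <- cands$chain[[i]]
      if (length(chain) != 1) next
      sites <- intersect(reg[[chain]]$site_tags, c("S", "H", "C"))
      for (s in sites) {
        ef <- expected_fragments(cands[i, ], s)
        sp <- spectrum(cands$`mz_[M+H]+`[i], 5, cbind(ef$mz, 100))
        expect_identical(infer_site(cands[i, ], sp)$site, s,
                         info = paste(parent_name, chain, s))
      }
    }
  }
})

test_that("soundness: the call never contradicts an observed status", {
  # evidence generated for S must make the H and C hypotheses inconsistent
  cands <- enumerate_candidates("ADMB-3TMS-PrINACA", max_steps = 1)
  hydroxy <- cands[cands$chain_class == "hydroxylation", ][1, ]
  ef <- expected_fragments(hydroxy, "S")
  sp <- spectrum(405.2316, 7.0, cbind(ef$mz, 100))
  call <- infer_site(hydroxy, sp)
  expect_identical(call$site, "S")
  # and mixed evidence from two different sites is undetermined
  ef_h <- expected_fragments(hydroxy, "H")
  mixed <- spectrum(405.2316, 7.0,
                    cbind(c(ef$mz[ef$shifted], ef_h$mz[!ef_h$shifted][1]),
                          100))
  expect_true(infer_site(hydroxy, mixed)$site %in% c("S", "undetermined"))
})

test_that("multi-step side-chain chains localize jointly to S", {
  cands <- enumerate_candidates("ADMB-3TMS-PrINACA", max_steps = 3)
  a10 <- cands[cands$chain_class ==
                 "carboxylic_acid_formation+cleavage_3tms_terminal_hydroxylation", ][1, ]
  ef <- expected_fragments(a10, "S")
  sp <- spectrum(347.1714, 2.97, cbind(ef$mz, 100))
  call <- infer_site(a10, sp)
  expect_identical(call$site, "S")
  expect_identical(call$per_step, c("S", "S"))
})

test_that("site annotations render for the report column", {
  cands <- enumerate_candidates("ADMB-3TMS-PrINACA", max_steps = 1)
  hydroxy <- cands[cands$chain_class == "hydroxylation", ][1, ]
  ef <- expected_fragments(hydroxy, "S")
  sp <- spectrum(405.2316, 7, cbind(ef$mz, 100))
  expect_identical(format_site_call(infer_site(hydroxy, sp)), "(S)")
  und <- infer_site(hydroxy, NULL)
  # the cleavage chain only permits the side chain: undetermined renders (S?)
  cl <- cands[cands$chain_class == "cleavage_3tms_terminal_hydroxylation", ][1, ]
  expect_identical(format_site_call(infer_site(cl, NULL), cl$chain[[1]]), "(S?)")
  expect_identical(format_site_call(und, hydroxy$chain[[1]]), "(?)")
})
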