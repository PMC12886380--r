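test_that("parent fragment inventories hold the curated diagnostic ions", {
  a <- parent_fragments("ADMB-3TMS-PrINACA")
  expect_true(all(c(73.0468, 145.0396, 259.1261, 344.2153) %in% round_mz(a$mz)))
  expect_true(277.1367 %in% a$mz[is.na(a$formula)])  # annotated literal
  c2 <- parent_fragments("Cumyl-3TMS-PrINACA")
  expect_true(all(c(73.0468, 91.0542, 119.0855, 145.0396, 259.1261) %in%
                    round_mz(c2$mz)))
  expect_error(parent_fragments("no-such-parent"), "unknown parent")
})

test_that("the identity chain returns the parent inventory unchanged", {
  cands <- enumerate_candidates("Cumyl-3TMS-PrINACA", max_steps = 0)
  ef <- expected_fragments(cands[1, ], "unknown")
  inv <- parent_fragments("Cumyl-3TMS-PrINACA")
  expect_identical(ef$name, inv$name)
  expect_identical(ef$mz, inv$mz)
  expect_false(any(ef$shifted))
})

test_that("hydroxylation shifts covered fragments by one oxygen (15.9949)", {
  cands <- enumerate_candidates("Cumyl-3TMS-PrINACA", max_steps = 1)
  hydroxy <- cands[cands$chain_class == "hydroxylation", ][1, ]
  side <- expected_fragments(hydroxy, "S")
  expect_equal(side$mz[side$name == "indazolyl_acylium_3tms"], 275.1210,
               tolerance = 2e-4)
  expect_equal(side$mz[side$name == "cumyl"], 119.0855, tolerance = 2e-4)
  head <- expected_fragments(hydroxy, "H")
  expect_equal(head$mz[head$name == "cumyl"], 135.0804, tolerance = 2e-4)
  expect_equal(head$mz[head$name == "cumyl"] -
                 side$mz[side$name == "cumyl"], 15.9949, tolerance = 2e-4)
  # fragments outside the site are identical to the parent's
  expect_identical(side$mz[!side$shifted],
                   parent_fragments("Cumyl-3TMS-PrINACA")$mz[
                     match(side$name[!side$shifted],
                           parent_fragments("Cumyl-3TMS-PrINACA")$name)])
})

test_that("3TMS cleavage chains produce the de-silylated ion series", {
  ac <- enumerate_candidates("ADMB-3TMS-PrINACA", max_steps = 3)
  a8 <- ac[ac$chain_class == "cleavage_3tms_terminal_hydroxylation", ][1, ]
  ef8 <- expected_fragments(a8, "S")
  expect_equal(sort(round_mz(ef8$mz)),
               sort(c(145.0396, 203.0815, 288.1707)), tolerance = 2e-4)
  expect_false("trimethylsilyl_cation" %in% ef8$name)  # TMS ion destroyed
  a10 <- ac[ac$chain_class ==
              "carboxylic_acid_formation+cleavage_3tms_terminal_hydroxylation", ][1, ]
  ef10 <- expected_fragments(a10, "S")
  expect_true(all(c(217.0608, 145.0396) %in% round_mz(ef10$mz)))
  cc <- enumerate_candidates("Cumyl-3TMS-PrINACA", max_steps = 3)
  c7 <- cc[cc$chain_class ==
             "cleavage_3tms_terminal_hydroxylation+ketone_aldehyde_formation", ][1, ]
  expect_true(any(abs(expected_fragments(c7, "S")$mz - 201.0658) < 2e-4))
})

test_that("core hydroxylation of dealkylated metabolites gives 161.0346", {
  ac <- enumerate_candidates("ADMB-3TMS-PrINACA", max_steps = 2)
  nd <- ac[ac$chain_class == "hydroxylation+n_dealkylation", ][1, ]
  ef <- expected_fragments(nd, "C")
  expect_true(any(abs(ef$mz - 161.0346) < 2e-4))
})

test_that("tabulated metabolite ions are generatable by some (chain, site)", {
  ac <- enumerate_candidates("ADMB-3TMS-PrINACA", max_steps = 3)
  cc <- enumerate_candidates("Cumyl-3TMS-PrINACA", max_steps = 3)
  generatable <- function(cands, chain_class, site, target) {
    cand <- cands[cands$chain_class == chain_class, ][1, ]
    ions <- c(expected_fragments(cand, site)$mz,
              inferred_class_ions(cand$parent_name, chain_class)$mz)
    any(abs(ions - target) < 2e-4)
  }
  # monohydroxylated side-chain species
  expect_true(generatable(ac, "hydroxylation", "S", 275.1210))
  expect_true(generatable(ac, "hydroxylation", "S", 293.1316))
  expect_true(generatable(ac, "hydroxylation", "S", 360.2102))
  # 3TMS-cleaved alcohol and acid
  expect_true(generatable(ac, "cleavage_3tms_terminal_hydroxylation", "S",
                          203.0815))
  expect_true(generatable(
    ac, "carboxylic_acid_formation+cleavage_3tms_terminal_hydroxylation", "S",
    217.0608))
  # cumyl panel
  expect_true(generatable(cc, "hydroxylation", "S", 275.1210))
  expect_true(generatable(cc, "hydroxylation", "S", 119.0855))
  expect_true(generatable(cc, "hydroxylation", "S", 145.0396))
})

test_that("inferred ions are flagged and never mistaken for curated ones", {
  inf <- inferred_class_ions("ADMB-3TMS-PrINACA")
  expect_gt(nrow(inf), 0)
  expect_true(all(vapply(inf$flags, function(f) "inferred" %in% f, logical(1))))
})

test_that("nominal EI fragment sets match the seized-material spectra", {
  a <- ei_nominal_fragments("ADMB-3TMS-PrINACA")
  c2 <- ei_nominal_fragments("Cumyl-3TMS-PrINACA")
  expect_true(all(c(73, 145, 259) %in% a))
  expect_true(all(c(73, 145, 259) %in% c2))
  expect_true(all(c(91, 119, 393) %in% c2))
  expect_false(119 %in% a)
  expect_error(ei_nominal_fragments("nope"), "unknown parent")
})
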