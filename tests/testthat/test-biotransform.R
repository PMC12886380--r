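test_that("single rule application matches the tabulated compositions", {
  a <- admb()
  c2 <- cumyl()
  expect_identical(
    apply_rule(a$composition, "cleavage_3tms_terminal_hydroxylation", a$tags),
    parse_formula("C17H24N4O3")
  )
  expect_identical(
    apply_rule(c2$composition, "hydroxylation", c2$tags),
    parse_formula("C23H31N3O2Si")
  )
})

test_that("unmet prerequisites are an error", {
  no_si <- parse_formula("C17H24N4O3")
  expect_error(
    apply_rule(no_si, "cleavage_3tms_terminal_hydroxylation", character()),
    "requires structural tag"
  )
  # silicon-free composition cannot even lose C3H8Si
  expect_error(
    apply_rule(no_si, "cleavage_3tms_terminal_hydroxylation", "requires_3TMS"),
    "negative count"
  )
})

test_that("enumeration at max_steps = 0 yields only the parent", {
  out <- enumerate_candidates("ADMB-3TMS-PrINACA", max_steps = 0)
  expect_identical(nrow(out), 1L)
  expect_identical(out$formula, "C20H32N4O2Si")
  expect_identical(out$chain[[1]], character())
})

test_that("a two-rule hydroxylation registry enumerates like brute force", {
  # brute-force oracle: all multisets of {hydroxylation} up to 2 applications
  reg <- default_rule_registry()["hydroxylation"]
  reg$hydroxylation$max_applications <- 2L
  class(reg) <- "rule_registry"
  out <- enumerate_candidates("ADMB-3TMS-PrINACA", registry = reg,
                              max_steps = 2)
  parent <- admb()$composition
  oracle <- vapply(0:2, function(k) {
    format_formula(Reduce(`+`, rep(list(parse_formula("O")), k), parent))
  }, character(1))
  expect_setequal(out$formula, oracle)
  expect_identical(nrow(out), 3L)
})

test_that("the default registry reproduces every tabulated composition", {
  admb_expected <- c("C20H32N4O2Si", "C20H32N4O3Si", "C20H32N4O4Si",
                     "C17H24N4O3", "C17H22N4O4", "C19H30N4O4Si")
  cumyl_expected <- c("C23H31N3OSi", "C23H31N3O2Si", "C22H29N3O2Si",
                      "C20H23N3O2", "C20H21N3O2", "C20H21N3O3",
                      "C22H29N3O3Si")
  a <- enumerate_candidates("ADMB-3TMS-PrINACA", max_steps = 3)
  c2 <- enumerate_candidates("Cumyl-3TMS-PrINACA", max_steps = 3)
  expect_true(all(admb_expected %in% a$formula))
  expect_true(all(cumyl_expected %in% c2$formula))
  # tabulated calculated [M+H]+ values, to 4 decimals
  calc <- function(df, f) round_mz(df$`mz_[M+H]+`[match(f, df$formula)])
  expect_equal(calc(a, c("C20H32N4O3Si", "C20H32N4O4Si", "C17H24N4O3",
                         "C17H22N4O4", "C19H30N4O4Si")),
               c(405.2316, 421.2266, 333.1921, 347.1714, 407.2109),
               tolerance = 2e-4)
  expect_equal(calc(c2, c("C23H31N3O2Si", "C22H29N3O2Si", "C20H23N3O2",
                          "C20H21N3O2", "C20H21N3O3", "C22H29N3O3Si")),
               c(410.2258, 396.2102, 338.1863, 336.1707, 352.1656, 412.2051),
               tolerance = 2e-4)
})

test_that("composition bookkeeping holds for every enumerated candidate", {
  reg <- default_rule_registry()
  for (parent_name in parent_compound()) {
    p <- parent_compound(parent_name)
    out <- enumerate_candidates(parent_name, max_steps = 3)
    for (i in seq_len(nrow(out))) {
      comp <- p$composition
      for (rn in out$chain[[i]]) comp <- comp + reg[[rn]]$gain - reg[[rn]]$loss
      expect_identical(format_formula(comp), out$formula[i],
                       info = out$candidate_key[i])
    }
  }
})

test_that("oxidation raises mass and demethylation lowers it by CH2", {
  reg <- default_rule_registry()
  a <- admb()
  base <- monoisotopic_mass(a$composition)
  for (rn in c("hydroxylation", "dihydroxylation", "trihydroxylation")) {
    expect_gt(monoisotopic_mass(apply_rule(a$composition, rn, a$tags)), base)
  }
  dm <- monoisotopic_mass(apply_rule(a$composition, "demethylation", a$tags))
  expect_equal(base - dm, 14.0157, tolerance = 1e-4)
})

test_that("enumeration is deterministic across runs", {
  a1 <- enumerate_candidates("Cumyl-3TMS-PrINACA", max_steps = 3)
  a2 <- enumerate_candidates("Cumyl-3TMS-PrINACA", max_steps = 3)
  expect_identical(a1$candidate_key, a2$candidate_key)
  expect_identical(a1$formula, a2$formula)
})

test_that("inclusion lists are sorted, complete, and carry both adducts", {
  cands <- enumerate_candidates("ADMB-3TMS-PrINACA", max_steps = 0)
  il <- build_inclusion_list(cands, adducts = c("[M+H]+", "[M+Na]+"))
  expect_identical(nrow(il), 2L)
  expect_equal(diff(il$mz), 21.9819, tolerance = 1e-4)
  full <- build_inclusion_list(enumerate_candidates("ADMB-3TMS-PrINACA",
                                                    max_steps = 3))
  expect_false(is.unsorted(full$mz))
  expect_true(any(abs(full$mz - 347.1714) < 2e-4))
  expect_error(build_inclusion_list(cands, adducts = character()), "empty")
  expect_error(build_inclusion_list(cands[0, ]), "empty")
})

test_that("silicon-to-carbon swap transfers counts and rewrites SMILES", {
  expect_identical(sila_swap(parse_formula("C20H32N4O2Si")),
                   parse_formula("C21H32N4O2"))
  expect_identical(sila_swap(parse_formula("C23H31N3OSi")),
                   parse_formula("C24H31N3O"))
  swapped <- sila_swap(admb()$smiles)
  expect_false(grepl("Si", swapped, fixed = TRUE))
  expect_identical(parse_smiles_min(swapped), parse_formula("C21H32N4O2"))
  expect_error(sila_swap(parse_formula("C17H24N4O3")), "no silicon")
})

test_that("aglycones undo O-glucuronidation", {
  cands <- enumerate_candidates("ADMB-3TMS-PrINACA", max_steps = 2)
  gluc <- cands[vapply(cands$chain, function(ch) {
    length(ch) > 0 && ch[length(ch)] == "o_glucuronidation"
  }, logical(1)), ][1, ]
  ag <- aglycone_of(gluc)
  expect_identical(
    parse_formula(ag$formula) + parse_formula("C6H8O6"),
    parse_formula(gluc$formula)
  )
  # glucuronide of the 3TMS-cleaved alcohol has the tabulated aglycone
  a <- admb()
  a8 <- apply_rule(a$composition, "cleavage_3tms_terminal_hydroxylation", a$tags)
  g <- a8 + parse_formula("C6H8O6")
  expect_identical(
    aglycone_of(list(parent_name = a$name, formula = format_formula(g),
                     chain = c("cleavage_3tms_terminal_hydroxylation",
                               "o_glucuronidation")))$formula,
    "C17H24N4O3"
  )
  parent_row <- cands[cands$chain_class == "", ]
  expect_error(aglycone_of(parent_row), "not an O-glucuronide")
})
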