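# Site labels used in reports vs the structural moieties a fragment covers.
.site_to_moiety <- c(S = "side_chain", H = "head_group", C = "core",
                     side_chain = "side_chain", head_group = "head_group",
                     core = "core", linker = "linker", unknown = "unknown")

# Rules that excise the silicon-bearing side chain act on every fragment
# whose cation contains Si, independent of the assumed site.
.si_excising_rules <- c("cleavage_3tms_terminal_hydroxylation", "n_dealkylation",
                        "si_demethylation")

# Fragments below the acquisition scan range, or stripped of all carbon,
# are not observable product ions.
.min_fragment_mz <- 50

#' Diagnostic fragment inventory of a parent compound
#'
#' Returns the curated diagnostic product-ion inventory for a parent: the
#' named cation compositions, derived m/z, and the structural moieties each
#' cation contains (which drives the fragment-shift localization logic).
#' The trimethylsilyl cation is tagged with the `side_chain_tms` sub-moiety:
#' a generic side-chain oxidation cannot be placed on the propyl versus the
#' trimethylsilyl part, so it leaves m/z 73.0468 unshifted, while rules that
#' excise the silicon remove it.
#'
#' @param parent_name Parent compound name (see [parent_compound()]).
#' @return A data.frame with columns `name`, `formula` (NA for annotated
#'   literal ions), `mz`, `moieties` (list column), `flags` (list column).
#' @examples
#' parent_fragments("Cumyl-3TMS-PrINACA")
#' @export
parent_fragments <- function(parent_name) {
  parent_compound(parent_name)  # validates the name
  kb <- .load_resource("fragment_kb.json")
  entries <- Filter(function(f) f$parent == parent_name, kb$fragments)
  if (length(entries) == 0) {
    stop("no fragment inventory for parent '", parent_name, "'", call. = FALSE)
  }
  rows <- lapply(entries, function(f) {
    moieties <- unlist(f$moieties)
    if (identical(moieties, "side_chain") && !is.null(f$composition) &&
        element_count(parse_formula(f$composition), "Si") > 0 &&
        element_count(parse_formula(f$composition), "C") <= 3) {
      moieties <- "side_chain_tms"
    }
    data.frame(
      name = f$name,
      formula = if (is.null(f$composition)) NA_character_ else f$composition,
      mz = if (is.null(f$composition)) f$literal_mz else cation_mz(f$composition),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$moieties <- lapply(entries, function(f) {
    m <- unlist(f$moieties)
    if (identical(m, "side_chain") && !is.null(f$composition) &&
        element_count(parse_formula(f$composition), "Si") > 0 &&
        element_count(parse_formula(f$composition), "C") <= 3) "side_chain_tms" else m
  })
  out$flags <- lapply(entries, function(f) unlist(f$flags) %||% character())
  stopifnot(all(out$mz > 0), all(lengths(out$moieties) > 0))
  rownames(out) <- NULL
  out
}

#' Inferred metabolite-class ions
#'
#' Curated ions observed for specific metabolite classes whose compositions
#' were back-calculated from the printed accurate mass (within 5 ppm) rather
#' than assigned structurally; they are flagged `"inferred"` and must not be
#' treated as ground truth.
#'
#' @param parent_name Parent compound name.
#' @param chain_class Canonical chain class (sorted rule names joined by
#'   `"+"`), or `NULL` for all classes.
#' @return Data.frame with `name`, `formula`, `mz`, `chain_class`, `flags`.
#' @export
inferred_class_ions <- function(parent_name, chain_class = NULL) {
  kb <- .load_resource("fragment_kb.json")
  entries <- Filter(function(f) {
    f$parent == parent_name &&
      (is.null(chain_class) || f$chain_class == chain_class)
  }, kb$inferred)
  if (length(entries) == 0) {
    return(data.frame(name = character(), formula = character(),
                      mz = numeric(), chain_class = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(entries, function(f) {
    data.frame(name = f$name, formula = f$composition,
               mz = cation_mz(f$composition), chain_class = f$chain_class,
               stringsAsFactors = FALSE)
  }))
  out$flags <- lapply(entries, function(f) unlist(f$flags))
  rownames(out) <- NULL
  out
}

.normalize_site <- function(site) {
  if (!site %in% names(.site_to_moiety)) {
    stop("unknown site label '", site,
         "'; expected one of S, H, C, core, side_chain, head_group, linker, unknown",
         call. = FALSE)
  }
  unname(.site_to_moiety[site])
}

#' Expected product ions of a candidate metabolite
#'
#' Predicts the product-ion m/z set for a candidate from its parent's
#' fragment inventory and its transformation chain: each parent fragment is
#' shifted by the summed composition deltas of the chain steps whose
#' (assumed) site lies within the fragment's covered moieties. Rules that
#' excise the silicon-bearing side chain (3TMS cleavage, N-dealkylation,
#' Si-demethylation) are applied to every Si-containing fragment regardless
#' of the assumed site; fragments whose residue falls below the scan range
#' or loses all carbon are dropped (e.g. the trimethylsilyl cation after
#' 3TMS cleavage). Annotated literal ions with no modeled composition are
#' kept for the identity chain and dropped once a covering shift applies.
#' O-glucuronides fragment like their aglycones, so the conjugation step
#' shifts nothing.
#'
#' @param candidate One row of [enumerate_candidates()] output (or a list
#'   with `parent_name` and `chain`).
#' @param sites Site label(s) for the chain steps: a single label recycled
#'   over the chain, or one label per step. `"unknown"` applies no generic
#'   shift (structural silicon rules still act).
#' @return Data.frame with `name`, `formula`, `mz`, `shifted` (logical),
#'   `moieties`, `flags`.
#' @examples
#' cands <- enumerate_candidates("Cumyl-3TMS-PrINACA", max_steps = 1)
#' hydroxy <- cands[cands$chain_class == "hydroxylation", ][1, ]
#' expected_fragments(hydroxy, "S")
#' @export
expected_fragments <- function(candidate, sites = "unknown") {
  if (is.data.frame(candidate)) {
    stopifnot(nrow(candidate) == 1)
    chain <- candidate$chain[[1]]
    parent_name <- candidate$parent_name
  } else {
    chain <- candidate$chain
    parent_name <- candidate$parent_name
  }
  registry <- default_rule_registry()
  inv <- parent_fragments(parent_name)
  if (length(chain) == 0) return(transform(inv, shifted = FALSE))
  sites <- vapply(as.character(sites), .normalize_site, character(1))
  if (length(sites) == 1) sites <- rep(sites, length(chain))
  if (length(sites) != length(chain)) {
    stop("sites must have length 1 or length(chain)", call. = FALSE)
  }

  keep <- logical(nrow(inv))
  out_formula <- inv$formula
  out_mz <- inv$mz
  shifted <- logical(nrow(inv))
  for (i in seq_len(nrow(inv))) {
    frag_formula <- inv$formula[i]
    moieties <- inv$moieties[[i]]
    dropped <- FALSE
    was_shifted <- FALSE
    for (k in seq_along(chain)) {
      rule <- registry[[chain[k]]]
      if (is.null(rule)) stop("unknown rule in chain: ", chain[k], call. = FALSE)
      if (rule$phase == "II") next  # conjugates fragment like the aglycone
      si_rule <- rule$name %in% .si_excising_rules
      applies <- if (si_rule) {
        if (is.na(frag_formula)) {
          # annotated literal ion: destroyed if it contains the side chain
          any(c("side_chain", "side_chain_tms") %in% moieties)
        } else {
          element_count(parse_formula(frag_formula), "Si") > 0
        }
      } else {
        sites[k] != "unknown" && sites[k] %in% moieties
      }
      if (!applies) next
      if (is.na(frag_formula)) { dropped <- TRUE; break }  # literal ion, unmodelable
      comp2 <- tryCatch(parse_formula(frag_formula) + rule$gain - rule$loss,
                        error = function(e) NULL)
      if (is.null(comp2) || element_count(comp2, "C") == 0 ||
          cation_mz(comp2) < .min_fragment_mz) {
        dropped <- TRUE
        break
      }
      frag_formula <- format_formula(comp2)
      was_shifted <- TRUE
    }
    if (!dropped) {
      keep[i] <- TRUE
      out_formula[i] <- frag_formula
      out_mz[i] <- if (is.na(frag_formula)) inv$mz[i] else cation_mz(frag_formula)
      shifted[i] <- was_shifted
    }
  }
  out <- inv[keep, , drop = FALSE]
  out$formula <- out_formula[keep]
  out$mz <- out_mz[keep]
  out$shifted <- shifted[keep]
  rownames(out) <- NULL
  out
}

#' Nominal GC-EI fragment set of a parent
#'
#' Electron-ionization spectra of the intact parents show a shared nominal
#' fragment set (trimethylsilyl 73; indazole-core 103, 131, 145; the
#' acylium-indazole-alkyl base peak 259); the cumyl-substituted parent adds
#' the tropylium (91) and cumyl (119) ions and its molecular ion (393).
#'
#' @param parent_name Parent compound name.
#' @return Sorted integer vector of nominal m/z values.
#' @examples
#' ei_nominal_fragments("Cumyl-3TMS-PrINACA")
#' @export
ei_nominal_fragments <- function(parent_name) {
  parent_compound(parent_name)  # validates
  kb <- .load_resource("fragment_kb.json")
  out <- unlist(kb$ei_nominal$shared)
  extra <- kb$ei_nominal[[parent_name]]
  if (!is.null(extra)) out <- c(out, unlist(extra))
  sort(as.integer(out))
}
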