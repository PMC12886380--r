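.moiety_to_site <- c(side_chain = "S", head_group = "H", core = "C")

# Per-step site options for a chain: structural silicon rules always act on
# the side chain; generic rules may act on any of their permitted site tags;
# phase II conjugation carries no site.
.site_options <- function(chain, registry) {
  lapply(chain, function(rule_name) {
    rule <- registry[[rule_name]]
    if (is.null(rule)) stop("unknown rule in chain: ", rule_name, call. = FALSE)
    if (rule$phase == "II") return(NA_character_)
    if (rule_name %in% .si_excising_rules) return("S")
    opts <- intersect(rule$site_tags, c("S", "H", "C"))
    if (length(opts) == 0) "S" else opts
  })
}

#' Infer the biotransformation site from fragment shifts
#'
#' Compares the observed product-ion spectrum against the fragment sets
#' expected under each site hypothesis (side chain S, head group H, core C;
#' one site per chain step, silicon-excising steps fixed to S). A hypothesis
#' is consistent when no observed fragment status contradicts it: a fragment
#' observed at its unaltered m/z contradicts a hypothesis expecting it
#' shifted, a fragment observed at a shifted m/z contradicts a hypothesis
#' expecting it unaltered, and an absent fragment is neutral evidence
#' (spectra may be incomplete). The site is called only if exactly one
#' hypothesis (per step) is consistent; otherwise `undetermined` — never an
#' exception.
#'
#' @param candidate One row of [enumerate_candidates()] output.
#' @param spec A [spectrum()] of the candidate's precursor (may be `NULL`).
#' @param tol_ppm Fragment tolerance in ppm (inclusive).
#' @return A list of class `site_call`: `site` (`"S"`, `"H"`, `"C"`, or
#'   `"undetermined"`), `per_step` (site per chain step, `NA` where
#'   undetermined), and `evidence` (data.frame `fragment`, `status`).
#' @examples
#' cands <- enumerate_candidates("Cumyl-3TMS-PrINACA", max_steps = 1)
#' hydroxy <- cands[cands$chain_class == "hydroxylation", ][1, ]
#' sp <- spectrum(410.2258, 13.2, cbind(c(275.1210, 119.0855, 145.0396),
#'                                      c(100, 80, 60)))
#' infer_site(hydroxy, sp)
#' @export
infer_site <- function(candidate, spec, tol_ppm = 10) {
  if (is.data.frame(candidate)) {
    stopifnot(nrow(candidate) == 1)
    chain <- candidate$chain[[1]]
    parent_name <- candidate$parent_name
  } else {
    chain <- candidate$chain
    parent_name <- candidate$parent_name
  }
  inv <- parent_fragments(parent_name)
  undetermined <- structure(
    list(site = "undetermined", per_step = rep(NA_character_, length(chain)),
         evidence = data.frame(fragment = character(), status = character(),
                               stringsAsFactors = FALSE)),
    class = "site_call"
  )
  if (length(chain) == 0) return(undetermined)
  registry <- default_rule_registry()
  options_per_step <- .site_options(chain, registry)
  free <- !vapply(options_per_step, function(o) all(is.na(o)), logical(1))
  if (!any(free)) return(undetermined)

  hyp_grid <- expand.grid(lapply(options_per_step, function(o) {
    if (all(is.na(o))) "unknown" else o
  }), stringsAsFactors = FALSE)
  hyp_expected <- lapply(seq_len(nrow(hyp_grid)), function(r) {
    expected_fragments(candidate, as.character(hyp_grid[r, ]))
  })

  peaks <- if (is.null(spec) || nrow(spec$peaks) == 0) numeric() else spec$peaks[, "mz"]
  seen <- function(target_mz) {
    length(peaks) > 0 && any(abs(ppm_error(peaks, target_mz)) <= tol_ppm)
  }

  # global, hypothesis-independent status per parent fragment: shifted if any
  # hypothesis' shifted variant is present, unshifted if the unaltered ion is
  shifted_variants <- lapply(inv$name, function(nm) {
    mzs <- unlist(lapply(hyp_expected, function(e) e$mz[e$name == nm & e$shifted]))
    unique(mzs)
  })
  status <- vapply(seq_len(nrow(inv)), function(i) {
    if (any(vapply(shifted_variants[[i]], seen, logical(1)))) return("shifted")
    if (seen(inv$mz[i])) return("unshifted")
    "absent"
  }, character(1))
  evidence <- data.frame(fragment = inv$name, status = status,
                         stringsAsFactors = FALSE)
  # no fragment observed at all: a site call needs positive evidence
  if (all(status == "absent")) return(.with_evidence(undetermined, evidence))

  consistent <- vapply(seq_len(nrow(hyp_grid)), function(r) {
    exp <- hyp_expected[[r]]
    for (i in seq_len(nrow(inv))) {
      nm <- inv$name[i]
      row <- exp[exp$name == nm, , drop = FALSE]
      if (nrow(row) == 0) next           # fragment destroyed: neutral
      if (row$shifted[1]) {
        if (seen(row$mz[1])) next        # expected shift observed
        # fragment seen, but not at the shift this hypothesis predicts
        if (status[i] %in% c("unshifted", "shifted")) return(FALSE)
      } else {
        if (status[i] == "shifted") return(FALSE)
      }
    }
    TRUE
  }, logical(1))

  if (!any(consistent)) return(.with_evidence(undetermined, evidence))
  ok <- hyp_grid[consistent, , drop = FALSE]
  per_step <- vapply(seq_len(ncol(ok)), function(k) {
    v <- unique(ok[[k]])
    if (length(v) == 1 && v != "unknown") v else NA_character_
  }, character(1))
  called <- per_step[!is.na(per_step) & free]
  site <- if (length(called) > 0 && !anyNA(per_step[free]) &&
              length(unique(per_step[free])) == 1) {
    unique(per_step[free])
  } else {
    "undetermined"
  }
  structure(list(site = site, per_step = per_step, evidence = evidence),
            class = "site_call")
}

.with_evidence <- function(call, evidence) {
  call$evidence <- evidence
  call
}

#' @export
print.site_call <- function(x, ...) {
  cat("<site_call> site:", x$site, "\n")
  if (length(x$per_step)) {
    cat("  per step:", paste(ifelse(is.na(x$per_step), "?", x$per_step),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

#' Format a site call for the report's transformation column
#'
#' `"(S)"` for a determined side-chain call, `"(S?)"` when undetermined but
#' the chain only permits the side chain, `"(?)"` otherwise.
#'
#' @param call A `site_call` from [infer_site()].
#' @param chain Transformation chain (rule names) of the candidate.
#' @return Short annotation string.
#' @export
format_site_call <- function(call, chain = NULL) {
  if (call$site != "undetermined") return(paste0("(", call$site, ")"))
  if (!is.null(chain) && length(chain)) {
    opts <- unique(unlist(.site_options(chain, default_rule_registry())))
    opts <- opts[!is.na(opts)]
    if (length(opts) == 1) return(paste0("(", opts, "?)"))
  }
  "(?)"
}
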