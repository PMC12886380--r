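#' Parent compound definitions
#'
#' Returns the built-in parent compound knowledge base entry: name, canonical
#' SMILES, Hill formula, composition, structural prerequisite tags for the
#' rule engine, metabolite-ID prefix, retention time, stage registry and
#' cross-reactivity registry.
#'
#' @param name Parent name (`"ADMB-3TMS-PrINACA"` or `"Cumyl-3TMS-PrINACA"`),
#'   or `NULL` to list all known parent names.
#' @return A list describing the parent, or a character vector of names.
#' @examples
#' parent_compound()
#' parent_compound("ADMB-3TMS-PrINACA")$formula
#' @export
parent_compound <- function(name = NULL) {
  raw <- .load_resource("parents.json")$parents
  known <- vapply(raw, function(p) p$name, character(1))
  if (is.null(name)) return(known)
  idx <- match(name, known)
  if (is.na(idx)) {
    stop("unknown parent compound '", name, "'; known: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  p <- raw[[idx]]
  list(
    name = p$name,
    label_prefix = p$label_prefix,
    smiles = p$smiles,
    formula = p$formula,
    composition = parse_formula(p$formula),
    tags = unlist(p$tags),
    rt_min = p$rt_min,
    stage_registry = stats::setNames(
      vapply(p$stage_registry, as.integer, integer(1)),
      names(p$stage_registry)
    ),
    cross_reactivity = lapply(p$cross_reactivity, unlist)
  )
}

#' Default biotransformation rule registry
#'
#' Loads the versioned JSON rule registry shipped with the package. Each
#' rule carries a composition `gain` and `loss`, a structural `prerequisite`
#' tag that must be present before the rule can be applied, tag updates
#' (`grants`, `revokes`) applied along a transformation chain, permitted
#' `site_tags` (S side chain, H head group, C core), the metabolic `phase`
#' (I or II) and a per-chain `max_applications` cap.
#'
#' @param path Optional path to an alternative registry JSON file.
#' @return A named list of rules (class `rule_registry`).
#' @examples
#' names(default_rule_registry())
#' @export
default_rule_registry <- function(path = NULL) {
  raw <- if (is.null(path)) {
    .load_resource("biotransform_rules.json")
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  rules <- lapply(raw$rules, function(r) {
    stopifnot(r$max_applications >= 1)
    list(
      name = r$name,
      gain = if (nzchar(r$gain)) parse_formula(r$gain) else composition(),
      loss = if (nzchar(r$loss)) parse_formula(r$loss) else composition(),
      prerequisite = r$prerequisite,
      grants = unlist(r$grants) %||% character(),
      revokes = unlist(r$revokes) %||% character(),
      site_tags = unlist(r$site_tags),
      phase = r$phase,
      max_applications = as.integer(r$max_applications),
      flags = unlist(r$flags) %||% character()
    )
  })
  names(rules) <- vapply(rules, function(r) r$name, character(1))
  structure(rules, registry_version = raw$registry_version, class = "rule_registry")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Apply one biotransformation rule to a composition
#'
#' @param comp A [composition()] (or formula string).
#' @param rule A rule from [default_rule_registry()], or its name.
#' @param prerequisites Character vector of structural tags currently present
#'   (e.g. `parent_compound("ADMB-3TMS-PrINACA")$tags`).
#' @return The transformed [composition()] (`comp + gain - loss`).
#' @examples
#' admb <- parent_compound("ADMB-3TMS-PrINACA")
#' apply_rule(admb$composition, "cleavage_3tms_terminal_hydroxylation",
#'            admb$tags)
#' @export
apply_rule <- function(comp, rule, prerequisites = character()) {
  comp <- .as_composition(comp)
  if (is.character(rule)) {
    registry <- default_rule_registry()
    if (!rule %in% names(registry)) stop("unknown rule '", rule, "'", call. = FALSE)
    rule <- registry[[rule]]
  }
  if (rule$prerequisite != "none" && !rule$prerequisite %in% prerequisites) {
    stop("rule '", rule$name, "' requires structural tag '", rule$prerequisite,
         "' which is not present", call. = FALSE)
  }
  comp + rule$gain - rule$loss
}

.update_tags <- function(tags, rule) {
  union(setdiff(tags, rule$revokes), rule$grants)
}

.chain_class <- function(rule_names) {
  paste(sort(rule_names), collapse = "+")
}

#' Enumerate candidate metabolites by breadth-first rule application
#'
#' Applies the rule registry to a parent compound up to `max_steps`
#' transformations, honoring structural prerequisites updated along the
#' chain (hydroxylation grants a hydroxyl for glucuronidation; 3TMS
#' cleavage revokes the silicon tags), a per-rule `max_applications` cap,
#' and deduplication by (composition, chain multiset) keeping the shortest
#' chain first encountered. The result is deterministically ordered by
#' monoisotopic mass, then chain length, then candidate key.
#'
#' @param parent A parent name (see [parent_compound()]) or a list with
#'   `name`, `composition`, and `tags`.
#' @param registry A [default_rule_registry()] (or subset of it).
#' @param max_steps Maximum chain length (>= 0; 0 returns only the parent).
#' @param phases Which metabolic phases to enumerate (`"I"`, `"II"` or both).
#' @param adducts Character vector of adduct names for which m/z values are
#'   attached to each candidate.
#' @return A data.frame of candidates with columns `candidate_key`,
#'   `parent_name`, `chain` (list of rule-name vectors), `chain_class`,
#'   `formula`, `phase`, `mass`, and one `mz_<adduct>` column per adduct.
#' @examples
#' head(enumerate_candidates("ADMB-3TMS-PrINACA", max_steps = 1))
#' @export
enumerate_candidates <- function(parent,
                                 registry = default_rule_registry(),
                                 max_steps = 3,
                                 phases = c("I", "II"),
                                 adducts = c("[M+H]+", "[M+Na]+")) {
  if (is.character(parent)) parent <- parent_compound(parent)
  if (length(registry) == 0) stop("rule registry is empty", call. = FALSE)
  if (max_steps < 0) stop("max_steps must be >= 0", call. = FALSE)
  registry <- registry[vapply(registry, function(r) r$phase %in% phases, logical(1))]

  # BFS over (composition, chain) states; dedup on (formula, chain multiset).
  seen <- new.env(parent = emptyenv())
  out <- list()
  push <- function(comp, chain, tags) {
    key <- paste0(format_formula(comp), "|", .chain_class(chain))
    if (!is.null(seen[[key]])) return(FALSE)
    seen[[key]] <- TRUE
    out[[length(out) + 1L]] <<- list(comp = comp, chain = chain, tags = tags)
    TRUE
  }
  push(parent$composition, character(), parent$tags)
  frontier <- list(list(comp = parent$composition, chain = character(),
                        tags = parent$tags))
  step <- 0L
  while (step < max_steps && length(frontier)) {
    step <- step + 1L
    nxt <- list()
    for (state in frontier) {
      for (rule in registry) {
        if (sum(state$chain == rule$name) >= rule$max_applications) next
        if (rule$prerequisite != "none" && !rule$prerequisite %in% state$tags) next
        comp2 <- tryCatch(state$comp + rule$gain - rule$loss,
                          error = function(e) NULL)
        if (is.null(comp2)) next  # loss not subtractable
        chain2 <- c(state$chain, rule$name)
        tags2 <- .update_tags(state$tags, rule)
        if (push(comp2, chain2, tags2)) {
          nxt[[length(nxt) + 1L]] <- list(comp = comp2, chain = chain2, tags = tags2)
        }
      }
    }
    frontier <- nxt
  }

  phase2_rules <- names(registry)[vapply(registry, function(r) r$phase == "II", logical(1))]
  rows <- lapply(out, function(s) {
    formula <- format_formula(s$comp)
    cls <- .chain_class(s$chain)
    data.frame(
      candidate_key = paste0(parent$name, "|", formula, "|", cls),
      parent_name = parent$name,
      chain_class = cls,
      formula = formula,
      phase = if (any(s$chain %in% phase2_rules)) "II" else "I",
      n_steps = length(s$chain),
      mass = monoisotopic_mass(s$comp),
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  df$chain <- lapply(out, function(s) s$chain)
  ord <- order(df$mass, df$n_steps, df$candidate_key)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  for (ad in adducts) {
    df[[paste0("mz_", ad)]] <- vapply(df$formula, function(f) mz(f, ad), numeric(1))
  }
  df
}

#' Build an auto-MS/MS inclusion list from enumerated candidates
#'
#' One row per candidate x adduct with the adduct m/z and an isolation
#' tolerance in ppm, sorted by ascending m/z.
#'
#' @param candidates Data.frame from [enumerate_candidates()].
#' @param adducts Character vector of adduct names (non-empty).
#' @param ppm_window Isolation tolerance in ppm attached to every row.
#' @return A data.frame with columns `candidate_key`, `adduct`, `mz`,
#'   `ppm_window` (class `inclusion_list`).
#' @examples
#' cands <- enumerate_candidates("ADMB-3TMS-PrINACA", max_steps = 1)
#' head(build_inclusion_list(cands))
#' @export
build_inclusion_list <- function(candidates, adducts = c("[M+H]+", "[M+Na]+"),
                                 ppm_window = 5) {
  if (is.null(candidates) || nrow(candidates) == 0) {
    stop("candidate list is empty", call. = FALSE)
  }
  if (length(adducts) == 0) stop("adduct list is empty", call. = FALSE)
  rows <- lapply(adducts, function(ad) {
    data.frame(
      candidate_key = candidates$candidate_key,
      adduct = ad,
      mz = vapply(candidates$formula, function(f) mz(f, ad), numeric(1)),
      ppm_window = ppm_window,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  stopifnot(all(out$mz > 0))
  out <- out[order(out$mz, out$candidate_key), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("inclusion_list", "data.frame")
  out
}

#' Silicon-to-carbon swap
#'
#' Replaces every silicon atom by carbon, either on a composition (count
#' transfer) or on a SMILES string (every `[Si]` token rewritten to `C`).
#' Used to probe in silico tools that cannot handle silicon.
#'
#' @param x A [composition()], formula string starting with a supported
#'   formula, or SMILES string containing `[Si]`.
#' @return Same kind as the input.
#' @examples
#' sila_swap(parse_formula("C20H32N4O2Si"))
#' sila_swap("O=C(C)[Si](C)(C)C")
#' @export
sila_swap <- function(x) {
  if (is_composition(x)) {
    n_si <- element_count(x, "Si")
    if (n_si == 0) stop("no silicon present", call. = FALSE)
    v <- unclass(x)
    v <- v[names(v) != "Si"]
    v["C"] <- (if ("C" %in% names(v)) v[["C"]] else 0L) + n_si
    return(composition(v))
  }
  if (is.character(x) && length(x) == 1) {
    if (grepl("[Si]", x, fixed = TRUE)) {
      return(gsub("[Si]", "C", x, fixed = TRUE))
    }
    comp <- tryCatch(parse_formula(x), error = function(e) NULL)
    if (!is.null(comp)) return(format_formula(sila_swap(comp)))
    stop("no silicon present", call. = FALSE)
  }
  stop("input must be a composition, formula, or SMILES string", call. = FALSE)
}

#' Aglycone of a glucuronide candidate
#'
#' For a phase II candidate whose chain ends with O-glucuronidation, returns
#' the corresponding phase I candidate: composition minus C6H8O6 and the
#' chain without the conjugation step.
#'
#' @param candidate One row of an [enumerate_candidates()] data.frame (as a
#'   data.frame of one row or a list with `formula`, `chain`, `parent_name`).
#' @return A list with `formula`, `composition`, `chain`, `chain_class`,
#'   `parent_name` describing the aglycone.
#' @export
aglycone_of <- function(candidate) {
  if (is.data.frame(candidate)) {
    stopifnot(nrow(candidate) == 1)
    chain <- candidate$chain[[1]]
    formula <- candidate$formula
    parent_name <- candidate$parent_name
  } else {
    chain <- candidate$chain
    formula <- candidate$formula
    parent_name <- candidate$parent_name
  }
  if (length(chain) == 0 || chain[length(chain)] != "o_glucuronidation") {
    stop("candidate is not an O-glucuronide (chain does not end with o_glucuronidation)",
         call. = FALSE)
  }
  comp <- parse_formula(formula) - parse_formula("C6H8O6")
  chain2 <- chain[-length(chain)]
  list(
    parent_name = parent_name,
    formula = format_formula(comp),
    composition = comp,
    chain = chain2,
    chain_class = .chain_class(chain2)
  )
}
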