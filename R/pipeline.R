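#' Default screening configuration
#'
#' Identification criteria and pipeline defaults: precursor mass error
#' strictly below 5 ppm, signal-to-noise strictly above 3, fragment mass
#' tolerance within 10 ppm (inclusive), at least one matched diagnostic
#' fragment, a 0.2 min retention-time window for isobar discrimination,
#' protonated and sodiated adducts, rule chains up to three steps, and
#' hydrolyzed mode (conjugates are cleaved before analysis, so phase II
#' candidates are screened as their aglycones, i.e. enumeration is phase I).
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of configuration values.
#' @export
screening_config <- function(...) {
  cfg <- list(
    ppm_tol = 5,            # precursor, strict <
    snr_min = 3,            # strict >
    fragment_tol_ppm = 10,  # inclusive
    min_matches = 1,        # diagnostic fragments required
    rt_window = 0.2,        # min, isobar discrimination
    spectrum_pairing_ppm = 10,
    spectrum_pairing_rt = 0.1,
    adducts = c("[M+H]+", "[M+Na]+"),
    max_steps = 3,
    hydrolyzed = TRUE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(cfg, over)
}

# Union of expected fragments over all site hypotheses of a candidate.
.expected_union <- function(candidate) {
  chain <- candidate$chain[[1]]
  if (length(chain) == 0) {
    ef <- expected_fragments(candidate, "unknown")
    return(unique(ef[, c("name", "mz")]))
  }
  registry <- default_rule_registry()
  opts <- .site_options(chain, registry)
  grid <- expand.grid(lapply(opts, function(o) {
    if (all(is.na(o))) "unknown" else o
  }), stringsAsFactors = FALSE)
  parts <- lapply(seq_len(nrow(grid)), function(r) {
    expected_fragments(candidate, as.character(grid[r, ]))[, c("name", "mz")]
  })
  unique(do.call(rbind, parts))
}

.nearest_spectrum <- function(spectra, feature_mz, feature_rt, ppm_tol, rt_tol) {
  if (length(spectra) == 0) return(NULL)
  prec <- vapply(spectra, function(s) s$precursor_mz, numeric(1))
  rts <- vapply(spectra, function(s) s$rt_min, numeric(1))
  ok <- abs(ppm_error(prec, feature_mz)) <= ppm_tol & abs(rts - feature_rt) <= rt_tol
  if (!any(ok)) return(NULL)
  idx <- which(ok)
  spectra[[idx[which.min(abs(prec[idx] - feature_mz))]]]
}

#' Run the full suspect-screening pipeline
#'
#' Orchestrates candidate enumeration, inclusion-list construction,
#' precursor matching under the identification criteria, retention-time
#' discrimination of isobars, diagnostic-fragment matching, site
#' localization, retention-time-ordered metabolite ID assignment, MAR
#' computation, and report assembly. Every rejected match is kept in the
#' rejection log with its reason.
#'
#' @param parent_name Parent compound to screen for.
#' @param features Feature table (data.frame or CSV path).
#' @param spectra Product-ion spectra (list of [spectrum()] or MGF path).
#' @param config A [screening_config()].
#' @return List with `candidates`, `inclusion`, `matches` (all precursor
#'   pairs), `identifications` (isobar-discriminated, fragment-evaluated),
#'   `accepted`, `ids`, `mar` (long format), `report` (wide rows ready for
#'   [write_report()]), and `log` (rejections with reasons).
#' @export
run_pipeline <- function(parent_name, features, spectra = list(),
                         config = screening_config()) {
  parent <- parent_compound(parent_name)
  if (is.character(features)) features <- read_feature_table(features)
  if (is.character(spectra)) spectra <- read_spectra(spectra)

  phases <- if (isTRUE(config$hydrolyzed)) "I" else c("I", "II")
  candidates <- enumerate_candidates(parent_name, max_steps = config$max_steps,
                                     phases = phases, adducts = config$adducts)
  inclusion <- build_inclusion_list(candidates, adducts = config$adducts,
                                    ppm_window = config$ppm_tol)
  empty_result <- list(candidates = candidates, inclusion = inclusion,
                       matches = NULL, identifications = NULL,
                       accepted = NULL, ids = NULL, mar = NULL,
                       report = .empty_report(), log = NULL,
                       parent_name = parent_name, config = config)
  if (nrow(features) == 0) {
    warning("empty feature table: nothing to screen", call. = FALSE)
    return(empty_result)
  }

  matches <- match_precursors(features, inclusion,
                              ppm_tol = config$ppm_tol,
                              snr_min = config$snr_min)
  if (nrow(matches) == 0) {
    warning("no features matched the inclusion list", call. = FALSE)
    return(empty_result)
  }
  idents <- discriminate_isobars(matches, rt_window = config$rt_window,
                                 candidates = candidates)

  # fragment stage + localization per identification
  idx <- match(idents$candidate_key, candidates$candidate_key)
  idents$chain_class <- candidates$chain_class[idx]
  idents$formula <- candidates$formula[idx]
  idents$phase <- candidates$phase[idx]
  rows <- vector("list", nrow(idents))
  for (i in seq_len(nrow(idents))) {
    row <- idents[i, , drop = FALSE]
    cand <- candidates[candidates$candidate_key == row$candidate_key, , drop = FALSE]
    sp <- .nearest_spectrum(spectra, row$mz, row$rt_min,
                            config$spectrum_pairing_ppm,
                            config$spectrum_pairing_rt)
    expected <- .expected_union(cand)
    row <- match_fragments(row, sp, expected,
                           tol_ppm = config$fragment_tol_ppm,
                           min_matches = config$min_matches)
    call <- if (row$accepted) infer_site(cand, sp, config$fragment_tol_ppm) else NULL
    row$site <- if (is.null(call)) NA_character_ else call$site
    row$site_annotation <- if (is.null(call)) {
      NA_character_
    } else {
      format_site_call(call, cand$chain[[1]])
    }
    rows[[i]] <- row
  }
  idents <- do.call(rbind, rows)

  accepted <- idents[idents$accepted, , drop = FALSE]
  log <- idents[!idents$accepted,
                c("sample_id", "matrix", "rt_min", "mz", "candidate_key",
                  "adduct", "ppm_error_precursor", "rejection_reason"),
                drop = FALSE]
  if (nrow(accepted) == 0) {
    out <- empty_result
    out$matches <- matches
    out$identifications <- idents
    out$log <- log
    return(out)
  }

  ids <- assign_ids(accepted, parent$stage_registry, parent$label_prefix,
                    rt_window = config$rt_window)
  accepted$label <- .label_for(accepted, ids, config$rt_window)
  accepted$is_parent <- accepted$chain_class == ""

  mar <- if (any(!accepted$is_parent)) {
    compute_mar(accepted, exclude_parent = TRUE)
  } else {
    NULL
  }

  report <- .build_report(accepted, ids, candidates, mar, parent)
  list(candidates = candidates, inclusion = inclusion, matches = matches,
       identifications = idents, accepted = accepted, ids = ids, mar = mar,
       report = report, log = log, parent_name = parent_name, config = config)
}

.label_for <- function(accepted, ids, rt_window) {
  vapply(seq_len(nrow(accepted)), function(i) {
    cand_ids <- ids[ids$candidate_key == accepted$candidate_key[i], , drop = FALSE]
    if (nrow(cand_ids) == 0) return(NA_character_)
    d <- abs(cand_ids$rt_min - accepted$rt_min[i])
    cand_ids$label[which.min(d)]
  }, character(1))
}

.empty_report <- function() {
  data.frame(ID = character(), rt_min = numeric(), transformation = character(),
             formula = character(), calc_mz_mh = numeric(), ppm_error = numeric(),
             diagnostic_ions = character(), stringsAsFactors = FALSE)
}

.pretty_chain <- function(chain) {
  if (length(chain) == 0) return("parent")
  pretty <- c(
    hydroxylation = "hydroxylation",
    dihydroxylation = "dihydroxylation",
    trihydroxylation = "trihydroxylation",
    ketone_aldehyde_formation = "ketone/aldehyde formation",
    carboxylic_acid_formation = "carboxylic acid formation",
    demethylation = "demethylation",
    si_demethylation = "Si-demethylation",
    cleavage_3tms_terminal_hydroxylation = "cleavage 3TMS + terminal hydroxylation",
    n_dealkylation = "N-dealkylation",
    amide_hydrolysis = "amide hydrolysis",
    o_glucuronidation = "O-glucuronidation"
  )
  paste(unname(pretty[chain]), collapse = " + ")
}

.build_report <- function(accepted, ids, candidates, mar, parent) {
  idx <- match(accepted$candidate_key, candidates$candidate_key)
  per_label <- split(seq_len(nrow(accepted)), accepted$label)
  rows <- lapply(per_label, function(ii) {
    i <- ii[1]
    cand <- candidates[idx[i], , drop = FALSE]
    frags <- unique(unlist(lapply(ii, function(k) {
      mf <- accepted$matched_fragments[[k]]
      if (is.null(mf) || nrow(mf) == 0) NULL else round_mz(mf$expected_mz)
    })))
    transformation <- if (accepted$is_parent[i]) {
      paste0(parent$name, " (parent)")
    } else {
      paste(.pretty_chain(cand$chain[[1]]),
            accepted$site_annotation[i])
    }
    data.frame(
      ID = accepted$label[i],
      rt_min = round(stats::median(accepted$rt_min[ii]), 2),
      transformation = transformation,
      formula = cand$formula,
      calc_mz_mh = round_mz(cand$`mz_[M+H]+`),
      ppm_error = round(stats::median(accepted$ppm_error_precursor[ii]), 2),
      diagnostic_ions = paste(sprintf("%.4f", sort(frags, decreasing = TRUE)),
                              collapse = "; "),
      parent_flag = if (accepted$is_parent[i]) "detected_not_in_MAR" else "",
      stringsAsFactors = FALSE
    )
  })
  report <- do.call(rbind, rows)
  if (!is.null(mar)) {
    for (m in unique(mar$matrix)) {
      col <- paste0("mar_", m)
      sub <- mar[mar$matrix == m, , drop = FALSE]
      report[[col]] <- round(sub$mar[match(report$ID, sub$label)], 2)
    }
  }
  report <- report[order(report$rt_min, report$ID), , drop = FALSE]
  rownames(report) <- NULL
  report
}

#' Rank urinary biomarkers by MAR
#'
#' Sorts the identified metabolites by urine MAR (descending), annotates
#' biomarkers shared with structurally related compounds as nonspecific,
#' and highlights the top three (the bold rows of an accurate-mass
#' metabolite table).
#'
#' @param mar Long-format MAR table from [compute_mar()].
#' @param cross_reactivity Registry from [parent_compound()] (may be empty).
#' @return Data.frame `label`, `mar_urine`, `rank`, `specificity`,
#'   `highlight`.
#' @export
rank_biomarkers <- function(mar, cross_reactivity = list()) {
  urine <- mar[mar$matrix == "urine", , drop = FALSE]
  if (nrow(urine) == 0) stop("no urine MAR data to rank", call. = FALSE)
  urine <- urine[order(-urine$mar, urine$label), , drop = FALSE]
  spec <- flag_specificity(urine$label, cross_reactivity)
  data.frame(
    label = urine$label,
    mar_urine = urine$mar,
    rank = seq_len(nrow(urine)),
    specificity = unname(spec),
    highlight = seq_len(nrow(urine)) <= 3,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Construct and validate a metabolic pathway graph
#'
#' Nodes are the parent plus candidate labels; edges are single rule
#' applications. Validation: the graph must be acyclic, every edge's rule
#' name must exist in the registry, and every non-root node must be
#' reachable from a root.
#'
#' @param nodes Data.frame with columns `name`, `root` (logical), `status`
#'   (`"detected"` or `"in_vitro_only"`).
#' @param edges Data.frame with columns `from`, `to`, `rule`.
#' @param registry Rule registry for edge validation.
#' @return List of class `pathway_graph` with `nodes`, `edges`, `graph`
#'   (an igraph object).
#' @export
pathway_graph <- function(nodes, edges,
                          registry = default_rule_registry()) {
  bad_rules <- setdiff(edges$rule, names(registry))
  if (length(bad_rules)) {
    stop("edge rule(s) not in the registry: ",
         paste(bad_rules, collapse = ", "), call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to"), drop = FALSE], directed = TRUE,
    vertices = nodes[, "name", drop = FALSE]
  )
  if (!igraph::is_dag(g)) stop("pathway graph contains a cycle", call. = FALSE)
  roots <- nodes$name[nodes$root]
  if (length(roots) == 0) stop("pathway graph has no root", call. = FALSE)
  reach <- unique(unlist(lapply(roots, function(r) {
    names(igraph::subcomponent(g, r, mode = "out"))
  })))
  unreachable <- setdiff(nodes$name, reach)
  if (length(unreachable)) {
    stop("node(s) unreachable from a root: ",
         paste(unreachable, collapse = ", "), call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "pathway_graph")
}

#' Export a metabolic pathway graph
#'
#' Builds the transformation graph for a set of labelled candidates (edges
#' follow chain prefixes: each metabolite hangs off the candidate one rule
#' shorter, or the parent) and writes GraphViz DOT and JSON renderings.
#' Detected nodes are drawn solid; in-vitro-only nodes dashed.
#'
#' @param candidates [enumerate_candidates()] output.
#' @param labels Named character vector candidate_key -> label for the
#'   candidates to include.
#' @param parent_name Parent compound name (graph root).
#' @param detected Labels detected in vivo (solid); all other labels are
#'   rendered dashed (in vitro only).
#' @param dot_path,json_path Optional output paths.
#' @return The validated [pathway_graph()], invisibly if files are written.
#' @export
export_pathway <- function(candidates, labels, parent_name,
                           detected = unname(labels),
                           dot_path = NULL, json_path = NULL) {
  keys <- names(labels)
  idx <- match(keys, candidates$candidate_key)
  if (anyNA(idx)) stop("labels refer to unknown candidate keys", call. = FALSE)
  chains <- candidates$chain[idx]
  parent <- parent_compound(parent_name)

  nodes <- data.frame(
    name = unique(c(paste0(parent$label_prefix, "0"), unname(labels))),
    stringsAsFactors = FALSE
  )
  nodes$root <- nodes$name == paste0(parent$label_prefix, "0")
  nodes$status <- ifelse(nodes$root | nodes$name %in% detected,
                         "detected", "in_vitro_only")

  class_of <- vapply(chains, .chain_class, character(1))
  edges <- do.call(rbind, lapply(seq_along(keys), function(i) {
    chain <- chains[[i]]
    if (length(chain) == 0) return(NULL)
    prefix_class <- .chain_class(chain[-length(chain)])
    from <- if (length(chain) == 1) {
      paste0(parent$label_prefix, "0")
    } else {
      hit <- which(class_of == prefix_class)
      if (length(hit)) unname(labels[hit[1]]) else paste0(parent$label_prefix, "0")
    }
    data.frame(from = from, to = unname(labels[i]),
               rule = chain[length(chain)], stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        rule = character(), stringsAsFactors = FALSE)
  }
  pg <- pathway_graph(nodes, edges)

  if (!is.null(dot_path)) {
    style <- ifelse(pg$nodes$status == "detected", "solid", "dashed")
    lines <- c(
      "digraph pathway {",
      "  rankdir=LR;",
      sprintf('  "%s" [style=%s%s];', pg$nodes$name, style,
              ifelse(pg$nodes$root, ", shape=box", "")),
      sprintf('  "%s" -> "%s" [label="%s"];', pg$edges$from, pg$edges$to,
              pg$edges$rule),
      "}"
    )
    writeLines(lines, dot_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(nodes = pg$nodes, edges = pg$edges), json_path,
                         dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  }
  if (is.null(dot_path) && is.null(json_path)) pg else invisible(pg)
}
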