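#' Parse a minimal SMILES subset into an elemental composition
#'
#' Supports exactly the grammar needed for the parent compounds handled by
#' this package and their carbon analogs: aliphatic atoms `C`, `N`, `O`,
#' aromatic atoms `c`, `n`, `o`, bracket atoms of any supported element
#' (e.g. `[Si]`, `[nH]`, optionally with an explicit hydrogen count such as
#' `[SiH3]`), single (`-`, implicit) and double (`=`) bonds, parenthesised
#' branches, and single-digit ring closures. Whitespace is ignored (some
#' published SMILES strings contain spaces around bond symbols). Charges,
#' isotopes, stereo marks, triple bonds, and multi-digit ring closures are
#' *not* supported and raise an "unsupported SMILES grammar" error rather
#' than being silently misparsed.
#'
#' Implicit hydrogens are filled from standard valences (C 4, N 3, O 2,
#' Si 4). Aromatic carbon contributes one implicit hydrogen unless
#' substituted (i.e. unless it has a third connection); aromatic nitrogen
#' and oxygen contribute none unless written `[nH]`.
#'
#' @param smiles SMILES string.
#' @return A [composition()] with heavy-atom and hydrogen counts.
#' @examples
#' parse_smiles_min("C")          # methane, CH4
#' parse_smiles_min("c1ccccc1")   # benzene, C6H6
#' @export
parse_smiles_min <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) || !nzchar(smiles)) {
    stop("SMILES must be a non-empty string", call. = FALSE)
  }
  s <- gsub("[[:space:]]", "", smiles)
  chars <- strsplit(s, "")[[1]]

  valence <- c(C = 4L, N = 3L, O = 2L, Si = 4L, S = 2L, P = 3L,
               F = 1L, Cl = 1L, Br = 1L, I = 1L)

  atoms <- list()   # each: symbol, aromatic, explicit_h (NA = fill), bondsum, degree
  prev <- NA_integer_
  pending_bond <- NA_integer_  # NA = default single/aromatic
  branch_stack <- integer()
  rings <- list()   # digit -> list(atom, bond)

  new_atom <- function(symbol, aromatic, explicit_h) {
    atoms[[length(atoms) + 1L]] <<- list(symbol = symbol, aromatic = aromatic,
                                         explicit_h = explicit_h,
                                         bondsum = 0, degree = 0L)
    length(atoms)
  }
  add_bond <- function(a, b, order) {
    # order NA: single unless both atoms aromatic (aromatic bond).
    aromatic_bond <- is.na(order) && atoms[[a]]$aromatic && atoms[[b]]$aromatic
    ord <- if (is.na(order)) 1 else order
    for (i in c(a, b)) {
      at <- atoms[[i]]
      at$degree <- at$degree + 1L
      # Aromatic atoms get hydrogens from the degree rule, so aromatic ring
      # bonds do not enter the valence bond sum; substituent bonds do.
      if (!(at$aromatic && aromatic_bond)) at$bondsum <- at$bondsum + ord
      atoms[[i]] <<- at
    }
  }
  connect <- function(idx) {
    force(idx)  # new_atom() must grow `atoms` before add_bond reads it
    if (!is.na(prev)) add_bond(prev, idx, pending_bond)
    prev <<- idx
    pending_bond <<- NA_integer_
  }
  fail <- function(what) {
    stop("unsupported SMILES grammar: ", what, " in '", smiles, "'", call. = FALSE)
  }

  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) fail("unclosed bracket atom")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec("^([A-Z][a-z]?|[cno])(H([0-9]?))?$", body))[[1]]
      if (length(m) == 0) fail(paste0("bracket atom [", body, "]"))
      sym <- m[2]
      aromatic <- sym %in% c("c", "n", "o")
      if (aromatic) sym <- toupper(sym)
      if (!sym %in% names(valence)) fail(paste0("element [", body, "]"))
      h <- if (nzchar(m[3])) {
        if (nzchar(m[4])) as.integer(m[4]) else 1L
      } else if (aromatic) 0L else NA_integer_
      connect(new_atom(sym, aromatic, h))
      i <- j + 1L
    } else if (ch %in% c("C", "N", "O", "S", "B")) {
      sym <- ch
      # two-letter organic-subset symbols (Cl, Br) would appear here; only
      # single-letter C/N/O are part of the supported grammar.
      if (i < n && chars[i + 1L] %in% setdiff(letters, c("c", "n", "o"))) {
        # lowercase that is not an aromatic atom: an unsupported two-letter
        # element symbol (Cl, Br, Sc, ...), outside the subset.
        fail(paste0("atom '", ch, chars[i + 1L], "'"))
      }
      if (!ch %in% c("C", "N", "O")) fail(paste0("atom '", ch, "'"))
      connect(new_atom(sym, FALSE, NA_integer_))
      i <- i + 1L
    } else if (ch %in% c("c", "n", "o")) {
      connect(new_atom(toupper(ch), TRUE, if (ch == "c") NA_integer_ else 0L))
      i <- i + 1L
    } else if (ch == "=") {
      pending_bond <- 2L
      i <- i + 1L
    } else if (ch == "-") {
      pending_bond <- 1L
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) fail("branch with no preceding atom")
      branch_stack <- c(branch_stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(branch_stack) == 0) fail("unbalanced ')'")
      prev <- branch_stack[length(branch_stack)]
      branch_stack <- branch_stack[-length(branch_stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      if (is.na(prev)) fail("ring closure with no preceding atom")
      key <- ch
      if (is.null(rings[[key]])) {
        rings[[key]] <- list(atom = prev, bond = pending_bond)
      } else {
        open <- rings[[key]]
        order <- if (!is.na(pending_bond)) pending_bond else open$bond
        add_bond(open$atom, prev, order)
        rings[[key]] <- NULL
      }
      pending_bond <- NA_integer_
      i <- i + 1L
    } else {
      fail(paste0("character '", ch, "'"))
    }
  }
  if (length(branch_stack)) fail("unbalanced '('")
  open_rings <- names(rings)[!vapply(rings, is.null, logical(1))]
  if (length(open_rings)) fail(paste0("unclosed ring bond(s) ", paste(open_rings, collapse = ",")))
  if (length(atoms) == 0) fail("no atoms")

  counts <- integer()
  h_total <- 0L
  for (at in atoms) {
    have <- counts[at$symbol]
    counts[at$symbol] <- (if (is.na(have)) 0L else have) + 1L
    h <- if (!is.na(at$explicit_h)) {
      at$explicit_h
    } else if (at$aromatic) {
      # aromatic C: one H unless substituted (third connection present)
      if (at$symbol == "C" && at$degree <= 2L) 1L else 0L
    } else {
      v <- valence[[at$symbol]]
      slack <- v - at$bondsum
      if (slack < 0) {
        stop("valence of ", at$symbol, " exceeded in '", smiles, "'", call. = FALSE)
      }
      as.integer(slack)
    }
    h_total <- h_total + h
  }
  if (h_total > 0) counts["H"] <- (if (is.na(counts["H"])) 0L else counts["H"]) + h_total
  composition(counts[!is.na(counts)])
}
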