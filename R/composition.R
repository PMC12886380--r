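#' Elemental composition
#'
#' An elemental composition is a map from element symbol to a non-negative
#' integer atom count. The supported element set is the one in
#' [mass_constants()] (C, H, N, O, Si, Na, S, P, F, Cl, Br, I). Compositions
#' support element-wise `+` and `-`; subtraction that would drive any count
#' negative is an error. Zero counts are dropped, so two compositions are
#' equal iff all stored counts agree.
#'
#' @param counts Named integer vector or named list of atom counts.
#' @return An object of class `composition` (named integer vector in Hill
#'   order: C, H, then remaining elements alphabetically).
#' @examples
#' composition(c(C = 3, H = 9, Si = 1))
#' composition(c(H = 2, O = 1)) + composition(c(O = 1))
#' @export
composition <- function(counts = integer()) {
  counts <- unlist(counts)
  if (length(counts) == 0) {
    out <- integer()
    class(out) <- "composition"
    return(out)
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("composition counts must be named by element symbol", call. = FALSE)
  }
  bad <- setdiff(names(counts), .supported_elements())
  if (length(bad)) {
    stop("unsupported element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("atom counts must be non-negative integers", call. = FALSE)
  }
  counts <- tapply(as.integer(counts), names(counts), sum)
  counts <- counts[counts > 0L]
  out <- as.integer(counts)
  names(out) <- names(counts)
  out <- out[.hill_order(names(out))]
  class(out) <- "composition"
  out
}

# Hill order: C first, H second, all other elements alphabetically.
.hill_order <- function(symbols) {
  rest <- sort(setdiff(symbols, c("C", "H")))
  match(intersect(c("C", "H", rest), symbols), symbols)
}

#' @export
print.composition <- function(x, ...) {
  cat("<composition> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' @export
Ops.composition <- function(e1, e2) {
  if (!.Generic %in% c("+", "-", "==", "!=")) {
    stop("operation '", .Generic, "' not defined for compositions", call. = FALSE)
  }
  a <- unclass(e1)
  b <- unclass(e2)
  elements <- union(names(a), names(b))
  av <- ifelse(elements %in% names(a), a[elements], 0L)
  bv <- ifelse(elements %in% names(b), b[elements], 0L)
  if (.Generic == "==") return(all(av == bv))
  if (.Generic == "!=") return(any(av != bv))
  res <- if (.Generic == "+") av + bv else av - bv
  if (any(res < 0)) {
    stop("composition subtraction would give a negative count for: ",
         paste(elements[res < 0], collapse = ", "), call. = FALSE)
  }
  names(res) <- elements
  composition(res[res > 0])
}

#' @rdname composition
#' @param x Object to test or coerce.
#' @export
is_composition <- function(x) inherits(x, "composition")

#' Atom count of one element
#'
#' @param comp A [composition()].
#' @param element Element symbol.
#' @return Integer count (0 if the element is absent).
#' @export
element_count <- function(comp, element) {
  stopifnot(is_composition(comp))
  v <- unclass(comp)
  if (element %in% names(v)) unname(v[[element]]) else 0L
}

#' Parse a Hill-style molecular formula
#'
#' Parses formulas such as `"C20H32N4O2Si"`: a concatenation of supported
#' element symbols, each followed by an optional positive integer count
#' (implicit 1). Unknown symbols, explicit zero counts, and empty strings
#' are rejected.
#'
#' @param text Formula string.
#' @return A [composition()].
#' @examples
#' parse_formula("C20H32N4O2Si")
#' parse_formula("C17H22N4O4")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text) || !nzchar(text)) {
    stop("formula must be a non-empty string", call. = FALSE)
  }
  tokens <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
  matched <- regmatches(text, list(tokens))[[1]]
  if (sum(nchar(matched)) != nchar(text)) {
    stop("malformed formula: ", text, call. = FALSE)
  }
  symbols <- sub("[0-9]*$", "", matched)
  counts <- sub("^[A-Z][a-z]?", "", matched)
  bad <- setdiff(symbols, .supported_elements())
  if (length(bad)) {
    stop("unknown element symbol(s) in formula: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- ifelse(nzchar(counts), suppressWarnings(as.integer(counts)), 1L)
  if (any(is.na(n)) || any(n <= 0)) {
    stop("element counts must be positive integers: ", text, call. = FALSE)
  }
  tab <- tapply(n, symbols, sum)
  composition(stats::setNames(as.integer(tab), names(tab)))
}

#' Format a composition as a canonical Hill-order formula
#'
#' Inverse of [parse_formula()]: `parse_formula(format_formula(x)) == x`.
#'
#' @param comp A [composition()].
#' @return Formula string ("" for the empty composition).
#' @examples
#' format_formula(composition(c(Si = 1, C = 3, H = 9)))
#' @export
format_formula <- function(comp) {
  stopifnot(is_composition(comp))
  v <- unclass(comp)
  if (length(v) == 0) return("")
  paste0(names(v), ifelse(v == 1L, "", v), collapse = "")
}
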