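#' Monoisotopic mass of a composition
#'
#' Sum over elements of count times the monoisotopic atomic mass from
#' [mass_constants()]. Additive over composition addition.
#'
#' @param comp A [composition()] (or formula string, parsed on the fly).
#' @return Mass in Da (0 for the empty composition).
#' @examples
#' monoisotopic_mass(parse_formula("H2O"))
#' @export
monoisotopic_mass <- function(comp) {
  comp <- .as_composition(comp)
  v <- unclass(comp)
  if (length(v) == 0) return(0)
  sum(v * mass_constants()$monoisotopic[names(v)])
}

#' Nominal (integer) mass of a composition
#'
#' @inheritParams monoisotopic_mass
#' @return Integer nominal mass (C 12, H 1, N 14, O 16, Si 28, ...).
#' @examples
#' nominal_mass(parse_formula("C23H31N3OSi"))  # 393
#' @export
nominal_mass <- function(comp) {
  comp <- .as_composition(comp)
  v <- unclass(comp)
  if (length(v) == 0) return(0L)
  as.integer(sum(v * mass_constants()$nominal[names(v)]))
}

.as_composition <- function(x) {
  if (is_composition(x)) x else parse_formula(x)
}

#' Adduct specification
#'
#' An adduct spec names the ion species formed from a neutral molecule M:
#' the composition gained and the (positive) charge. The m/z computation in
#' [mz()] subtracts `charge` electron masses. Built-in names: `"[M+H]+"`
#' and `"[M+Na]+"`; the m/z difference between them is the fixed constant
#' 21.9819 for any M.
#'
#' @param name Adduct name, e.g. `"[M+H]+"`.
#' @param delta A [composition()] gained by the molecule (for custom adducts).
#' @param charge Positive integer charge.
#' @return A list of class `adduct_spec` with fields `name`, `delta`, `charge`.
#' @examples
#' adduct("[M+Na]+")
#' @export
adduct <- function(name, delta = NULL, charge = NULL) {
  builtin <- list(
    "[M+H]+"  = list(delta = composition(c(H = 1)),  charge = 1L),
    "[M+Na]+" = list(delta = composition(c(Na = 1)), charge = 1L)
  )
  if (is.null(delta)) {
    if (!name %in% names(builtin)) {
      stop("unknown adduct '", name, "'; supply delta and charge explicitly",
           call. = FALSE)
    }
    delta <- builtin[[name]]$delta
    charge <- builtin[[name]]$charge
  }
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) stop("adduct charge must be >= 1", call. = FALSE)
  structure(list(name = name, delta = .as_composition(delta), charge = charge),
            class = "adduct_spec")
}

#' m/z of an adduct ion
#'
#' Computes `(mass(M) + mass(delta) - charge * m_e) / charge` for a neutral
#' molecule M and an adduct specification. Electron mass is subtracted
#' because the printed accurate masses of cations are only reproducible
#' that way.
#'
#' @param comp Neutral molecule composition (or formula string).
#' @param adduct An [adduct()] spec or adduct name string.
#' @return m/z value (full precision; see [round_mz()] for table-style
#'   4-decimal reporting).
#' @examples
#' mz("C20H32N4O2Si", "[M+H]+")  # 389.2367
#' @export
mz <- function(comp, adduct = "[M+H]+") {
  comp <- .as_composition(comp)
  if (is.character(adduct)) adduct <- silascreen::adduct(adduct)
  stopifnot(inherits(adduct, "adduct_spec"))
  el <- mass_constants()$electron
  (monoisotopic_mass(comp) + monoisotopic_mass(adduct$delta) -
      adduct$charge * el) / adduct$charge
}

#' m/z of a singly charged cation from its atom inventory
#'
#' For fragment cations whose composition is given as the atom inventory of
#' the ion itself (e.g. the trimethylsilyl cation C3H9Si+), the m/z is the
#' monoisotopic mass minus one electron mass.
#'
#' @inheritParams monoisotopic_mass
#' @return m/z value.
#' @examples
#' cation_mz("C3H9Si")  # 73.0468
#' @export
cation_mz <- function(comp) {
  monoisotopic_mass(.as_composition(comp)) - mass_constants()$electron
}

#' Signed ppm mass error
#'
#' `1e6 * (observed - calculated) / calculated`.
#'
#' @param observed Observed m/z.
#' @param calculated Calculated m/z (> 0).
#' @return Signed error in ppm.
#' @examples
#' ppm_error(389.23865, 389.2367)
#' @export
ppm_error <- function(observed, calculated) {
  if (any(!is.finite(calculated)) || any(calculated <= 0)) {
    stop("calculated m/z must be positive", call. = FALSE)
  }
  1e6 * (observed - calculated) / calculated
}

#' Round an m/z value to reporting precision
#'
#' Reports m/z half-even to 4 decimals, mirroring the accurate-mass tables
#' this package reproduces.
#'
#' @param x Numeric m/z value(s).
#' @param digits Decimal places (default 4).
#' @return Rounded numeric.
#' @export
round_mz <- function(x, digits = 4) round(x, digits)
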