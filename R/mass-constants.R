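# Package-level cache for the JSON resources shipped under inst/extdata.
.silascreen <- new.env(parent = emptyenv())

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "silascreen")
  if (!nzchar(path)) stop("resource file not found: ", file, call. = FALSE)
  path
}

.load_resource <- function(file) {
  key <- paste0("res_", file)
  if (is.null(.silascreen[[key]])) {
    .silascreen[[key]] <- jsonlite::read_json(.extdata(file), simplifyVector = FALSE)
  }
  .silascreen[[key]]
}

#' Monoisotopic mass constants
#'
#' Returns the immutable table of monoisotopic atomic masses (Da), integer
#' nominal masses, and the electron mass used by all mass arithmetic in the
#' package. Values follow CODATA/IUPAC recommendations and are documented to
#' at least six decimal places in the shipped JSON resource
#' (`extdata/mass_constants.json`).
#'
#' @return A list with components `monoisotopic` (named numeric vector, Da),
#'   `nominal` (named integer vector), and `electron` (numeric, Da).
#' @examples
#' mass_constants()$monoisotopic[["Si"]]
#' @export
mass_constants <- function() {
  if (is.null(.silascreen$constants)) {
    raw <- .load_resource("mass_constants.json")
    .silascreen$constants <- list(
      monoisotopic = unlist(raw$monoisotopic),
      nominal = unlist(raw$nominal),
      electron = raw$electron
    )
  }
  .silascreen$constants
}

.supported_elements <- function() names(mass_constants()$monoisotopic)
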