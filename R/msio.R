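.feature_columns <- c("sample_id", "matrix", "rt_min", "mz", "area", "snr")
.known_matrices <- c("urine", "pHLM", "PHH", "blood", "gastric", "synthetic")

#' Validate a feature table
#'
#' A feature table holds one row per chromatographic peak: `sample_id`,
#' `matrix` (urine, pHLM, PHH, blood, gastric, synthetic), `rt_min`
#' (minutes, >= 0), `mz` (> 0), `area` (>= 0, arbitrary units), `snr`
#' (signal-to-noise, >= 0). Malformed input is rejected, never coerced.
#'
#' @param features Data.frame to validate.
#' @return The validated data.frame (invisibly usable in pipelines).
#' @export
validate_features <- function(features) {
  missing_cols <- setdiff(.feature_columns, names(features))
  if (length(missing_cols)) {
    stop("feature table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num <- c("rt_min", "mz", "area", "snr")
  for (col in num) {
    if (!is.numeric(features[[col]]) || any(is.na(features[[col]]))) {
      stop("feature column '", col, "' must be numeric with no missing values",
           call. = FALSE)
    }
  }
  if (any(features$rt_min < 0)) stop("rt_min must be >= 0", call. = FALSE)
  if (any(features$mz <= 0)) stop("mz must be > 0", call. = FALSE)
  if (any(features$area < 0)) stop("area must be >= 0", call. = FALSE)
  if (any(features$snr < 0)) stop("snr must be >= 0", call. = FALSE)
  bad <- setdiff(unique(features$matrix), .known_matrices)
  if (length(bad)) {
    stop("unknown matrix value(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(.known_matrices, collapse = ", "),
         call. = FALSE)
  }
  features
}

#' Read an LC-MS feature table from CSV
#'
#' @param path CSV file with header columns `sample_id, matrix, rt_min, mz,
#'   area, snr`. Row order is preserved.
#' @return Validated data.frame of features.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_features(df)
}

#' Write an LC-MS feature table to CSV
#'
#' @param features Feature data.frame (validated on write).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  features <- validate_features(features)
  out <- features[, .feature_columns, drop = FALSE]
  # fixed formatting keeps identical config + seed => byte-identical files
  out$rt_min <- formatC(out$rt_min, format = "f", digits = 4)
  out$mz <- formatC(out$mz, format = "f", digits = 6)
  out$area <- formatC(out$area, format = "f", digits = 4)
  out$snr <- formatC(out$snr, format = "f", digits = 4)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a product-ion spectrum
#'
#' @param precursor_mz Precursor m/z (> 0).
#' @param rt_min Retention time in minutes (>= 0).
#' @param peaks Two-column matrix or data.frame of (mz, intensity);
#'   sorted by m/z on construction.
#' @param collision_energy Collision energy in eV (metadata only).
#' @param title Spectrum title.
#' @return Object of class `spectrum`.
#' @export
spectrum <- function(precursor_mz, rt_min, peaks,
                     collision_energy = NA_real_, title = "") {
  stopifnot(is.numeric(precursor_mz), precursor_mz > 0, rt_min >= 0)
  peaks <- as.matrix(peaks)
  if (length(peaks) == 0) {
    peaks <- matrix(numeric(), ncol = 2)
  }
  if (ncol(peaks) != 2) stop("peaks must have two columns (mz, intensity)", call. = FALSE)
  colnames(peaks) <- c("mz", "intensity")
  if (any(peaks[, "intensity"] < 0)) stop("peak intensities must be >= 0", call. = FALSE)
  peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
  structure(list(precursor_mz = precursor_mz, rt_min = rt_min, peaks = peaks,
                 collision_energy = collision_energy, title = title),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> precursor m/z %.4f, rt %.2f min, %d peaks\n",
              x$precursor_mz, x$rt_min, nrow(x$peaks)))
  invisible(x)
}

#' Read product-ion spectra
#'
#' Reads MGF (`BEGIN IONS`/`END IONS` blocks with `PEPMASS` and
#' `RTINSECONDS`; retention times are converted to minutes) or, when the
#' `mzR` package is available, centroided mzML. Peak lists are sorted on
#' load; malformed blocks and profile-mode mzML are rejected.
#'
#' @param path Input file.
#' @param format `"MGF"` or `"mzML"` (default guessed from the extension).
#' @return List of [spectrum()] objects.
#' @export
read_spectra <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzML" else "MGF"
  }
  switch(toupper(format),
         MGF = .read_mgf(path),
         MZML = .read_mzml(path),
         stop("unsupported spectra format '", format, "'", call. = FALSE))
}

.read_mgf <- function(path) {
  lines <- readLines(path)
  spectra <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (line == "BEGIN IONS") {
      precursor <- NA_real_
      rt_sec <- NA_real_
      ce <- NA_real_
      title <- ""
      peaks <- list()
      i <- i + 1L
      closed <- FALSE
      while (i <= n) {
        line <- trimws(lines[i])
        i <- i + 1L
        if (line == "END IONS") { closed <- TRUE; break }
        if (!nzchar(line)) next
        if (grepl("^[A-Z_]+=", line)) {
          key <- sub("=.*$", "", line)
          value <- sub("^[A-Z_]+=", "", line)
          if (key == "PEPMASS") {
            precursor <- suppressWarnings(as.numeric(strsplit(value, "[ \t]+")[[1]][1]))
          } else if (key == "RTINSECONDS") {
            rt_sec <- suppressWarnings(as.numeric(value))
          } else if (key == "COLLISION_ENERGY") {
            ce <- suppressWarnings(as.numeric(value))
          } else if (key == "TITLE") {
            title <- value
          }  # other keys (CHARGE, SCANS, ...) ignored
        } else {
          fields <- suppressWarnings(as.numeric(strsplit(line, "[ \t]+")[[1]]))
          if (length(fields) < 2 || any(is.na(fields[1:2]))) {
            stop("malformed MGF peak line: '", line, "'", call. = FALSE)
          }
          peaks[[length(peaks) + 1L]] <- fields[1:2]
        }
      }
      if (!closed) stop("malformed MGF: BEGIN IONS without END IONS", call. = FALSE)
      if (is.na(precursor)) stop("malformed MGF: block without PEPMASS", call. = FALSE)
      peak_mat <- if (length(peaks)) do.call(rbind, peaks) else matrix(numeric(), ncol = 2)
      spectra[[length(spectra) + 1L]] <- spectrum(
        precursor_mz = precursor,
        rt_min = if (is.na(rt_sec)) 0 else rt_sec / 60,
        peaks = peak_mat,
        collision_energy = ce,
        title = title
      )
    } else if (nzchar(line)) {
      stop("malformed MGF: unexpected content outside BEGIN/END IONS: '",
           line, "'", call. = FALSE)
    } else {
      i <- i + 1L
    }
  }
  spectra
}

.read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the 'mzR' package; use MGF instead",
         call. = FALSE)
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  if (any(hdr$centroided == FALSE, na.rm = TRUE)) {
    stop("profile-mode mzML is not supported; centroid the data first",
         call. = FALSE)
  }
  idx <- which(hdr$msLevel >= 2)
  lapply(idx, function(i) {
    pk <- mzR::peaks(handle, i)
    spectrum(
      precursor_mz = hdr$precursorMZ[i],
      rt_min = hdr$retentionTime[i] / 60,
      peaks = pk,
      collision_energy = hdr$collisionEnergy[i]
    )
  })
}

#' Write spectra to MGF
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output MGF path.
#' @return `path`, invisibly.
#' @export
write_spectra_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (sp in spectra) {
    stopifnot(inherits(sp, "spectrum"))
    writeLines("BEGIN IONS", con)
    if (nzchar(sp$title)) writeLines(paste0("TITLE=", sp$title), con)
    writeLines(sprintf("PEPMASS=%.6f", sp$precursor_mz), con)
    writeLines(sprintf("RTINSECONDS=%.4f", sp$rt_min * 60), con)
    if (!is.na(sp$collision_energy)) {
      writeLines(sprintf("COLLISION_ENERGY=%.1f", sp$collision_energy), con)
    }
    if (nrow(sp$peaks)) {
      writeLines(sprintf("%.6f %.4f", sp$peaks[, "mz"], sp$peaks[, "intensity"]), con)
    }
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

.report_columns <- c("ID", "rt_min", "transformation", "formula",
                     "calc_mz_mh", "ppm_error", "diagnostic_ions")

#' Write an identification report
#'
#' Writes the screening report in the layout of the accurate-mass metabolite
#' tables this package reproduces: metabolite ID, retention time,
#' transformation with site annotation, elemental composition, calculated
#' protonated m/z, observed mass error (ppm), diagnostic product ions, and
#' one MAR column per matrix (`mar_<matrix>`).
#'
#' @param rows Report data.frame (see [run_pipeline()]).
#' @param path Output path.
#' @param format `"TSV"` or `"JSON"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path, format = c("TSV", "JSON")) {
  format <- match.arg(format)
  base <- intersect(.report_columns, names(rows))
  mar_cols <- grep("^mar_", names(rows), value = TRUE)
  extra <- setdiff(names(rows), c(base, mar_cols))
  rows <- rows[, c(base, mar_cols, extra), drop = FALSE]
  if (format == "TSV") {
    utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(rows, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  }
  invisible(path)
}

#' Read back an identification report
#'
#' @param path Report path written by [write_report()].
#' @param format `"TSV"` or `"JSON"`.
#' @return Data.frame of report rows.
#' @export
read_report <- function(path, format = c("TSV", "JSON")) {
  format <- match.arg(format)
  if (format == "TSV") {
    utils::read.delim(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}
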