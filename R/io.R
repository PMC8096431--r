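# Readers and writers for the plain-text interchange formats: plate CSV,
# feature-table CSV, compound-library CSV, CFU CSV, MGF stick spectra, and
# JSON reports. Schema validation errors name the offending column/row.

read_checked_csv <- function(path, required, numeric_cols = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(basename(path), " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (cn in intersect(numeric_cols, names(df))) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(conv))
      if (length(bad)) {
        stop(basename(path), ": non-numeric value in column '", cn,
             "', row ", bad[1], ": '", v[bad[1]], "'")
      }
      df[[cn]] <- conv
    }
  }
  tibble::as_tibble(df)
}

#' Read a plate fluorescence CSV
#'
#' Expected header: `well_id, role, compound_a, conc_a, compound_b, conc_b,
#' replicate, fluorescence`.
#'
#' @param path CSV file path.
#' @return A validated plate table.
#' @export
read_plate_csv <- function(path) {
  df <- read_checked_csv(
    path,
    required = c("well_id", "role", "compound_a", "conc_a", "compound_b",
                 "conc_b", "replicate", "fluorescence"),
    numeric_cols = c("conc_a", "conc_b", "replicate", "fluorescence"))
  validate_plate_table(df)
}

#' Read an LC-MS feature table CSV
#'
#' Expected columns: `feature_id`, `mz`, `rt`, plus one `intensity_<run>`
#' and optionally one `has_ms2_<run>` column per run.
#'
#' @param path CSV file path.
#' @return Feature table tibble.
#' @export
read_feature_csv <- function(path) {
  df <- read_checked_csv(path, required = c("feature_id", "mz", "rt"),
                         numeric_cols = c("mz", "rt"))
  icols <- grep("^intensity_", names(df), value = TRUE)
  if (!length(icols)) {
    stop(basename(path), " has no intensity_<run> columns")
  }
  for (cn in c(icols, grep("^has_ms2_", names(df), value = TRUE))) {
    df[[cn]] <- as.numeric(df[[cn]])
  }
  df
}

#' Read a compound library CSV
#'
#' Expected columns: `name, family, monoisotopic_mass, is_polyene,
#' reference_rt, standard_available`.
#'
#' @param path CSV file path.
#' @return Library tibble.
#' @export
read_library_csv <- function(path) {
  df <- read_checked_csv(
    path,
    required = c("name", "family", "monoisotopic_mass", "is_polyene",
                 "reference_rt", "standard_available"),
    numeric_cols = c("monoisotopic_mass", "reference_rt"))
  df$is_polyene <- as.logical(df$is_polyene)
  df$standard_available <- as.logical(df$standard_available)
  if (any(df$monoisotopic_mass <= 0)) {
    stop("nonpositive monoisotopic mass in library")
  }
  df
}

#' Read a CFU count table CSV
#'
#' Expected columns: `organism, treatment, replicate, cfu_initial,
#' cfu_final`.
#'
#' @param path CSV file path.
#' @return CFU tibble.
#' @export
read_cfu_csv <- function(path) {
  read_checked_csv(
    path,
    required = c("organism", "treatment", "replicate", "cfu_initial",
                 "cfu_final"),
    numeric_cols = c("replicate", "cfu_initial", "cfu_final"))
}

#' Write and read MGF stick spectra
#'
#' Minimal MGF dialect: one `BEGIN IONS`/`END IONS` block per spectrum with
#' a `TITLE=<feature_id>` line and `mz intensity` fragment rows.
#'
#' @param spectra Named list of two-column matrices keyed by feature id.
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(spectra)) {
    sp <- as_spectrum(spectra[[id]])
    writeLines(c("BEGIN IONS", paste0("TITLE=", id),
                 sprintf("%.6f %.6f", sp[, 1], sp[, 2]),
                 "END IONS", ""), con)
  }
  invisible(path)
}

#' @rdname write_mgf
#' @return `read_mgf` returns the named list of spectra.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (lines[i] == "BEGIN IONS") {
      j <- i + 1L
      title <- NULL
      frags <- list()
      while (j <= length(lines) && lines[j] != "END IONS") {
        if (startsWith(lines[j], "TITLE=")) {
          title <- sub("^TITLE=", "", lines[j])
        } else if (grepl("^[0-9]", lines[j])) {
          frags[[length(frags) + 1L]] <-
            as.numeric(strsplit(trimws(lines[j]), "[ \t]+")[[1]][1:2])
        }
        j <- j + 1L
      }
      if (j > length(lines)) stop("unterminated IONS block at line ", i)
      if (is.null(title)) stop("IONS block without TITLE at line ", i)
      m <- do.call(rbind, frags)
      colnames(m) <- c("mz", "intensity")
      out[[title]] <- m
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Write a result table as CSV and JSON
#'
#' Floating-point values are serialized at full precision (no digit
#' rounding) so reports are stable and reloadable.
#'
#' @param x Data frame or named list.
#' @param stem Output path without extension; writes `<stem>.csv` (for data
#'   frames) and `<stem>.json`.
#' @export
write_report <- function(x, stem) {
  dir.create(dirname(stem), showWarnings = FALSE, recursive = TRUE)
  if (is.data.frame(x)) {
    df <- as.data.frame(x)
    df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
    utils::write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
  }
  jsonlite::write_json(x, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(stem)
}
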