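# The spectrum_set container: one spectral modality's wavenumber grid,
# sample x channel intensity matrix, and an append-only preprocessing
# provenance trail.

#' Construct a spectrum set
#'
#' A `spectrum_set` holds the spectra of one modality: a strictly monotone
#' wavenumber grid (cm^-1), an intensity matrix with one row per sample,
#' and the ordered list of preprocessing operators already applied.
#'
#' @param wavenumbers Strictly monotone numeric vector (cm^-1).
#' @param intensities Numeric matrix, one row per sample, `length(wavenumbers)`
#'   columns.
#' @param sample_ids Character vector of row identifiers.
#' @param modality One of `"nir_trans"`, `"nir_refl"`, `"raman_trans"`,
#'   `"raman_refl"` (or any label for ad hoc sets).
#' @param provenance List of applied operator records (name + parameters).
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(wavenumbers, intensities, sample_ids = NULL,
                         modality = "unknown", provenance = list()) {
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != length(wavenumbers))
    stop("column count (", ncol(intensities), ") must equal wavenumber length (",
         length(wavenumbers), ")")
  dw <- diff(wavenumbers)
  if (length(dw) && !(all(dw > 0) || all(dw < 0)))
    stop("wavenumbers must be strictly monotone")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(intensities)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(intensities)))
  }
  if (length(sample_ids) != nrow(intensities))
    stop("sample_ids length must match row count")
  rownames(intensities) <- sample_ids
  structure(
    list(wavenumbers = as.numeric(wavenumbers), intensities = intensities,
         sample_ids = as.character(sample_ids), modality = modality,
         provenance = provenance),
    class = "spectrum_set"
  )
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("<spectrum_set> modality:", x$modality, "\n")
  cat("  ", nrow(x$intensities), "samples x", length(x$wavenumbers),
      "channels [", min(x$wavenumbers), "-", max(x$wavenumbers), "cm^-1 ]\n")
  ops <- vapply(x$provenance, function(p) p$op, character(1))
  cat("  provenance:", if (length(ops)) paste(ops, collapse = " -> ") else "(raw)", "\n")
  invisible(x)
}

# internal: return a copy with one provenance record appended
append_provenance <- function(s, op, params = list()) {
  s$provenance <- c(s$provenance, list(c(list(op = op), params)))
  s
}

#' Write / read spectra as delimited text
#'
#' CSV layout: first column `tablet_id`, remaining column names are the
#' wavenumber grid; one row per tablet.
#'
#' @param s A `spectrum_set`.
#' @param path Output file.
#' @return `write_spectra_csv` returns `path` invisibly; `read_spectra_csv`
#'   returns a `spectrum_set`.
#' @export
write_spectra_csv <- function(s, path) {
  stopifnot(inherits(s, "spectrum_set"))
  df <- data.frame(tablet_id = s$sample_ids, s$intensities,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("tablet_id", format(s$wavenumbers, trim = TRUE, scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @param modality Modality tag to attach on read.
#' @export
read_spectra_csv <- function(path, modality = "unknown") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(colnames(df)[1], "tablet_id"))
    stop("spectra CSV must have 'tablet_id' as its first column: ", path)
  wn <- suppressWarnings(as.numeric(colnames(df)[-1]))
  if (anyNA(wn))
    stop("non-numeric wavenumber header in ", path, " at column ",
         which(is.na(wn))[1] + 1L)
  dw <- diff(wn)
  if (length(dw) && !(all(dw > 0) || all(dw < 0)))
    stop("wavenumber header is not strictly monotone in ", path, " near column ",
         which(diff(sign(dw)) != 0)[1] + 1L)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric intensity cells in ", path)
  spectrum_set(wn, m, sample_ids = df$tablet_id, modality = modality)
}
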