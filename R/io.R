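#' Read and write the spectra CSV dialect
#'
#' The on-disk format is a plain CSV with a header row of
#' `sample_id, class_id, drug_id` followed by one column per wavenumber
#' channel, labeled with its wavenumber in cm^-1 to 2 decimals, strictly
#' increasing left to right; each subsequent row is one spectrum. On read,
#' the grid is reconstructed from the first and last channel labels and the
#' channel count, and every label is checked against it to within the label
#' precision. Absorbances are written at full double precision so a
#' write/read round trip reproduces values to better than 1e-9.
#'
#' @param dataset A [spectral_dataset()].
#' @param path File path.
#' @return `read_spectra()` returns a `"spectral_dataset"`;
#'   `write_spectra()` its `path`, invisibly.
#' @export
write_spectra <- function(dataset, path) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  wn <- wavenumbers(dataset$grid)
  df <- data.table::data.table(sample_id = dataset$sample_id,
                               class_id = dataset$class_id,
                               drug_id = dataset$drug_id)
  mat <- data.table::as.data.table(dataset$x)
  data.table::setnames(mat, sprintf("%.2f", wn))
  data.table::fwrite(cbind(df, mat), path)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = TRUE)
  if (nrow(dt) == 0L) stop("no spectra found in ", path)
  need <- c("sample_id", "class_id", "drug_id")
  if (!all(need %in% names(dt)[1:3]))
    stop("missing required leading columns: expected ",
         paste(need, collapse = ", "))
  labels <- suppressWarnings(as.numeric(names(dt)[-(1:3)]))
  if (length(labels) < 2L || anyNA(labels))
    stop("channel columns must be labeled with numeric wavenumbers")
  if (any(diff(labels) <= 0))
    stop("channel columns must be strictly increasing in wavenumber")
  grid <- wavenumber_grid(labels[1], labels[length(labels)], length(labels))
  if (max(abs(wavenumbers(grid) - labels)) > 0.006)
    stop("channel labels are not an evenly spaced wavenumber grid")
  x <- as.matrix(dt[, -(1:3)])
  if (!is.numeric(x)) stop("non-numeric absorbance values")
  bad <- which(!stats::complete.cases(x) | rowSums(!is.finite(x)) > 0)
  if (length(bad))
    stop("malformed spectra at data row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  dimnames(x) <- NULL
  spectral_dataset(x, dt$class_id, dt$drug_id, grid = grid,
                   sample_id = dt$sample_id)
}
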