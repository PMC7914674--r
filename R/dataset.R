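#' Spectral dataset container
#'
#' Holds N absorbance spectra on a shared wavenumber grid together with
#' per-row manufacturer class ids, drug-family ids and sample ids.
#'
#' @param x Numeric matrix, N rows (spectra) by L channels; finite, no NA.
#' @param class_id Integer vector of length N (1-based class ids).
#' @param drug_id Integer vector of length N (drug-family ids).
#' @param grid A [wavenumber_grid()] with `n_channels == ncol(x)`.
#' @param catalog Optional `"class_catalog"`; when given, every `class_id`
#'   must occur in it.
#' @param sample_id Character vector of length N (default `"s00001"`, ...).
#' @return An object of class `"spectral_dataset"`.
#' @export
spectral_dataset <- function(x, class_id, drug_id, grid,
                             catalog = NULL, sample_id = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x) || !all(is.finite(x)))
    stop("spectra must be a finite numeric matrix without missing values")
  n <- nrow(x)
  class_id <- as.integer(class_id)
  drug_id <- as.integer(drug_id)
  stopifnot(length(class_id) == n, length(drug_id) == n,
            inherits(grid, "wavenumber_grid"))
  if (grid$n_channels != ncol(x))
    stop("grid has ", grid$n_channels, " channels but spectra have ", ncol(x))
  if (!is.null(catalog)) {
    stopifnot(inherits(catalog, "class_catalog"))
    if (!all(class_id %in% catalog$class_id))
      stop("dataset contains class ids absent from the catalog")
  }
  if (is.null(sample_id)) sample_id <- sprintf("s%05d", seq_len(n))
  stopifnot(length(sample_id) == n)
  structure(list(x = x, class_id = class_id, drug_id = drug_id,
                 sample_id = as.character(sample_id), grid = grid,
                 catalog = catalog),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("Spectral dataset: %d spectra x %d channels, %d classes, %d drug families\n",
              nrow(x$x), ncol(x$x), length(unique(x$class_id)),
              length(unique(x$drug_id))))
  print(x$grid)
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$x)

#' Subset a spectral dataset by row
#'
#' @param x A `"spectral_dataset"`.
#' @param i Row indices (integer or logical).
#' @param ... Unused.
#' @return A `"spectral_dataset"` with the selected rows.
#' @export
`[.spectral_dataset` <- function(x, i, ...) {
  spectral_dataset(x$x[i, , drop = FALSE], x$class_id[i], x$drug_id[i],
                   grid = x$grid, catalog = x$catalog,
                   sample_id = x$sample_id[i])
}

#' @export
as.matrix.spectral_dataset <- function(x, ...) x$x

#' @export
plot.spectral_dataset <- function(x, rows = seq_len(min(20L, nrow(x$x))),
                                  ...) {
  wn <- wavenumbers(x$grid)
  graphics::matplot(wn, t(x$x[rows, , drop = FALSE]), type = "l", lty = 1,
                    col = x$class_id[rows],
                    xlab = expression(Wavenumber ~ (cm^-1)),
                    ylab = "Absorbance", ...)
  invisible(x)
}
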