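#' Wavenumber grid
#'
#' Defines the shared spectral x-axis: `n_channels` evenly spaced wavenumbers
#' between `start` and `end` (cm^-1), inclusive. The default grid spans the
#' NIR range 4000--11995 cm^-1 with 2074 channels, matching the input width
#' of the networks in [bigan_config()].
#'
#' @param start,end Range of the grid in cm^-1; `start < end`.
#' @param n_channels Number of channels (>= 2).
#' @return An object of class `"wavenumber_grid"`.
#' @examples
#' g <- wavenumber_grid()
#' length(wavenumbers(g))
#' @export
wavenumber_grid <- function(start = 4000, end = 11995, n_channels = 2074) {
  stopifnot(is.numeric(start), is.numeric(end), length(start) == 1L,
            length(end) == 1L, is.finite(start), is.finite(end))
  if (!(start < end)) stop("'start' must be strictly less than 'end'")
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels < 2L) stop("'n_channels' must be >= 2")
  structure(list(start = as.numeric(start), end = as.numeric(end),
                 n_channels = n_channels),
            class = "wavenumber_grid")
}

#' @rdname wavenumber_grid
#' @param grid A `"wavenumber_grid"`.
#' @export
wavenumbers <- function(grid) {
  stopifnot(inherits(grid, "wavenumber_grid"))
  seq(grid$start, grid$end, length.out = grid$n_channels)
}

#' @export
print.wavenumber_grid <- function(x, ...) {
  cat(sprintf("Wavenumber grid: %.2f-%.2f cm^-1, %d channels (spacing %.3f cm^-1)\n",
              x$start, x$end, x$n_channels,
              (x$end - x$start) / (x$n_channels - 1L)))
  invisible(x)
}
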