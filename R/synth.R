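#' Drug family archetypes
#'
#' Draws one spectral archetype per drug family: a set of Gaussian absorbance
#' bands (center, width, height) on a linear baseline. Archetypes of
#' different families are guaranteed to differ in at least one band center
#' by more than that band's width, so families are separable while sharing
#' the broad-band character of NIR diffuse-reflectance spectra.
#'
#' @param n_drugs Number of drug families (>= 1).
#' @param grid A [wavenumber_grid()].
#' @param n_peaks Bands per archetype (default 8).
#' @param seed Integer seed; fixed seed gives identical archetypes.
#' @return A list of `n_drugs` archetypes, each a list with `peak_centers`,
#'   `peak_widths`, `peak_heights` (all length `n_peaks`) and
#'   `baseline = c(offset, slope)`.
#' @export
drug_archetypes <- function(n_drugs, grid = wavenumber_grid(), n_peaks = 8L,
                            seed = 1L) {
  stopifnot(inherits(grid, "wavenumber_grid"), n_drugs >= 1L, n_peaks >= 1L)
  span <- grid$end - grid$start
  margin <- 0.03 * span
  draw_one <- function() {
    list(peak_centers = stats::runif(n_peaks, grid$start + margin, grid$end - margin),
         peak_widths = stats::runif(n_peaks, 0.01 * span, 0.035 * span),
         peak_heights = stats::runif(n_peaks, 0.10, 0.90),
         baseline = c(stats::runif(1, 0.05, 0.30),
                      stats::runif(1, -0.1, 0.1) / span))
  }
  # two archetypes are "separated" when one has a band whose center is more
  # than its own width away from every band of the other
  separated <- function(a, b) {
    any(vapply(seq_along(a$peak_centers), function(i) {
      min(abs(a$peak_centers[i] - b$peak_centers)) > a$peak_widths[i]
    }, logical(1)))
  }
  set.seed(as.integer(seed))
  arch <- vector("list", n_drugs)
  for (d in seq_len(n_drugs)) {
    for (try in seq_len(200L)) {
      cand <- draw_one()
      ok <- all(vapply(arch[seq_len(d - 1L)], function(p)
        separated(cand, p) && separated(p, cand), logical(1)))
      if (ok) break
    }
    if (!ok) stop("could not draw pairwise-separated archetypes")
    arch[[d]] <- cand
  }
  arch
}

#' Manufacturer profiles
#'
#' Derives one manufacturer profile per catalog class by perturbing the
#' archetype of its drug family: per-band multiplicative height changes,
#' small band-center shifts, a baseline offset and a global multiplicative
#' scatter coefficient. All perturbation magnitudes are bounded by
#' `manufacturer_effect`, so with `manufacturer_effect = 0` all profiles of
#' a family are identical and as it grows manufacturers become easier to
#' tell apart.
#'
#' @param archetypes List of archetypes from [drug_archetypes()]; one per
#'   drug family id occurring in `catalog`.
#' @param catalog A `"class_catalog"`.
#' @param manufacturer_effect Nonnegative perturbation scale (default 0.05).
#' @param seed Integer seed.
#' @return A list of profiles (one per class, in class_id order), each a
#'   list with `class_id`, `drug_id`, `archetype`, `height_deltas`,
#'   `center_shifts`, `baseline_delta`, `scatter_coeff`.
#' @export
manufacturer_profiles <- function(archetypes, catalog,
                                  manufacturer_effect = 0.05, seed = 1L) {
  stopifnot(inherits(catalog, "class_catalog"), manufacturer_effect >= 0)
  drugs <- sort(unique(catalog$drug_id))
  if (max(drugs) > length(archetypes))
    stop("catalog refers to drug family ", max(drugs), " but only ",
         length(archetypes), " archetypes were given")
  set.seed(as.integer(seed))
  eff <- manufacturer_effect
  lapply(seq_len(nrow(catalog)), function(i) {
    a <- archetypes[[catalog$drug_id[i]]]
    np <- length(a$peak_centers)
    list(class_id = catalog$class_id[i],
         drug_id = catalog$drug_id[i],
         archetype = a,
         height_deltas = 1 + eff * stats::runif(np, -1, 1),
         center_shifts = eff * 100 * stats::runif(np, -1, 1),
         baseline_delta = eff * 0.1 * stats::runif(1, -1, 1),
         scatter_coeff = 1 + 0.5 * eff * stats::runif(1, -1, 1))
  })
}

#' Noiseless class spectrum of a manufacturer profile
#'
#' @param profile One element of [manufacturer_profiles()].
#' @param grid A [wavenumber_grid()].
#' @return Numeric vector of length `grid$n_channels`.
#' @export
profile_curve <- function(profile, grid = wavenumber_grid()) {
  wn <- wavenumbers(grid)
  a <- profile$archetype
  y <- a$baseline[1] + profile$baseline_delta + a$baseline[2] * (wn - grid$start)
  for (i in seq_along(a$peak_centers)) {
    ctr <- a$peak_centers[i] + profile$center_shifts[i]
    y <- y + a$peak_heights[i] * profile$height_deltas[i] *
      exp(-(wn - ctr)^2 / (2 * a$peak_widths[i]^2))
  }
  profile$scatter_coeff * y
}

#' Simulate a multi-manufacturer NIR spectra dataset
#'
#' Generates, for every class of `catalog`, exactly `n_samples` spectra
#' from the class's noiseless profile curve under an EMSC-style
#' per-spectrum measurement model:
#'
#'   `x = curve * (1 + s)  +  a + b * t  +  noise`
#'
#' where `s ~ N(0, scatter_sd^2)` is multiplicative scatter
#' (diffuse-reflectance pathlength variability), `a ~ N(0, drift_sd^2)` a
#' baseline offset and `b ~ N(0, tilt_sd^2)` a baseline tilt over the
#' normalized wavenumber `t` in `[0, 1]` (instrument and background
#' drift), and the last term is i.i.d. additive Gaussian channel noise
#' with standard deviation `noise_sd` (detector noise). With all four
#' dispersion parameters at 0 every spectrum of a class is identical; with
#' the same seed the dataset is bit-reproducible.
#'
#' @param profiles Profiles from [manufacturer_profiles()].
#' @param catalog A `"class_catalog"`.
#' @param noise_sd Additive per-channel noise sd (absorbance units).
#' @param scatter_sd Sd of the per-spectrum multiplicative scatter factor.
#' @param drift_sd Sd of the per-spectrum baseline offset (absorbance
#'   units).
#' @param tilt_sd Sd of the per-spectrum baseline tilt (absorbance units
#'   across the full grid).
#' @param outlier_prob Probability that a spectrum is an outlier
#'   measurement (poor probe contact or positioning), in which case its
#'   scatter, offset and tilt draws are inflated by `outlier_scale`.
#' @param outlier_scale Nuisance inflation factor for outlier spectra.
#' @param grid A [wavenumber_grid()].
#' @param seed Integer seed.
#' @return A [spectral_dataset()].
#' @examples
#' ds <- simulate_dataset(seed = 7, grid = wavenumber_grid(n_channels = 64))
#' ds
#' @export
simulate_spectra <- function(profiles, catalog, noise_sd = 0.005,
                             scatter_sd = 0.1, drift_sd = 0.05,
                             tilt_sd = 0.05, outlier_prob = 0.15,
                             outlier_scale = 6, grid = wavenumber_grid(),
                             seed = 1L) {
  stopifnot(inherits(catalog, "class_catalog"), noise_sd >= 0,
            scatter_sd >= 0, drift_sd >= 0, tilt_sd >= 0,
            outlier_prob >= 0, outlier_prob <= 1, outlier_scale >= 1)
  if (length(profiles) != nrow(catalog))
    stop("need exactly one profile per catalog class")
  set.seed(as.integer(seed))
  L <- grid$n_channels
  tnorm <- seq(0, 1, length.out = L)
  total <- sum(catalog$n_samples)
  x <- matrix(0, nrow = total, ncol = L)
  cls <- integer(total)
  drg <- integer(total)
  row <- 0L
  for (i in seq_len(nrow(catalog))) {
    curve <- profile_curve(profiles[[i]], grid)
    n <- catalog$n_samples[i]
    infl <- ifelse(stats::runif(n) < outlier_prob, outlier_scale, 1)
    scatter <- 1 + stats::rnorm(n, 0, scatter_sd) * infl
    offs <- stats::rnorm(n, 0, drift_sd) * infl
    tilt <- stats::rnorm(n, 0, tilt_sd) * infl
    noise <- matrix(stats::rnorm(n * L, 0, noise_sd), nrow = n)
    x[row + seq_len(n), ] <- scatter %o% curve + outer(offs, rep(1, L)) +
      tilt %o% tnorm + noise
    cls[row + seq_len(n)] <- catalog$class_id[i]
    drg[row + seq_len(n)] <- catalog$drug_id[i]
    row <- row + n
  }
  spectral_dataset(x, cls, drg, grid = grid, catalog = catalog,
                   sample_id = sprintf("s%05d", seq_len(total)))
}

#' One-call synthetic dataset with the bundled catalog
#'
#' Convenience wrapper chaining [drug_archetypes()],
#' [manufacturer_profiles()] and [simulate_spectra()] under substreams of a
#' single seed. Defaults emulate the bundled 29-manufacturer study:
#' near-identical within-family spectra with subtle manufacturer
#' differences and realistic instrument noise.
#'
#' @inheritParams simulate_spectra
#' @inheritParams manufacturer_profiles
#' @param catalog A `"class_catalog"` (default [drug_catalog()]).
#' @return A [spectral_dataset()].
#' @export
simulate_dataset <- function(catalog = drug_catalog(),
                             grid = wavenumber_grid(),
                             manufacturer_effect = 0.6,
                             noise_sd = 0.005, scatter_sd = 0.1,
                             drift_sd = 0.05, tilt_sd = 0.05,
                             outlier_prob = 0.15, outlier_scale = 6,
                             seed = 1L) {
  arch <- drug_archetypes(length(unique(catalog$drug_id)), grid,
                          seed = substream_seed(seed, "archetypes"))
  prof <- manufacturer_profiles(arch, catalog, manufacturer_effect,
                                seed = substream_seed(seed, "profiles"))
  simulate_spectra(prof, catalog, noise_sd = noise_sd,
                   scatter_sd = scatter_sd, drift_sd = drift_sd,
                   tilt_sd = tilt_sd, outlier_prob = outlier_prob,
                   outlier_scale = outlier_scale, grid = grid,
                   seed = substream_seed(seed, "spectra"))
}
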