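test_that("archetypes are deterministic, in range and pairwise separated", {
  g <- tiny_grid()
  a1 <- drug_archetypes(4, g, seed = 1)
  a2 <- drug_archetypes(4, g, seed = 1)
  expect_identical(a1, a2)
  for (a in a1) {
    expect_true(all(a$peak_centers >= g$start & a$peak_centers <= g$end))
    expect_true(all(a$peak_widths > 0))
    expect_true(all(a$peak_heights >= 0))
  }
  # pairwise separation: some band center differs by more than its width
  for (i in 1:3) for (j in (i + 1):4) {
    sep <- any(vapply(seq_along(a1[[i]]$peak_centers), function(p)
      min(abs(a1[[i]]$peak_centers[p] - a1[[j]]$peak_centers)) >
        a1[[i]]$peak_widths[p], logical(1)))
    expect_true(sep)
  }
  # different seeds give different archetypes essentially always
  draws <- vapply(1:20, function(s)
    drug_archetypes(1, g, seed = s)[[1]]$peak_centers[1], numeric(1))
  expect_gt(length(unique(round(draws, 6))), 15)
})

test_that("zero manufacturer effect collapses same-drug profiles", {
  g <- tiny_grid()
  arch <- drug_archetypes(2, g, seed = 2)
  cat4 <- tiny_catalog()
  prof <- manufacturer_profiles(arch, cat4, manufacturer_effect = 0, seed = 9)
  c1 <- profile_curve(prof[[1]], g)
  c2 <- profile_curve(prof[[2]], g)
  expect_identical(c1, c2)   # same drug, zero effect
  expect_false(isTRUE(all.equal(profile_curve(prof[[3]], g), c1)))  # other drug
  # determinism under a fixed seed
  prof2 <- manufacturer_profiles(arch, cat4, manufacturer_effect = 0.05,
                                 seed = 7)
  prof3 <- manufacturer_profiles(arch, cat4, manufacturer_effect = 0.05,
                                 seed = 7)
  expect_identical(prof2, prof3)
})

test_that("same-drug class means are more alike than cross-drug means", {
  g <- tiny_grid()
  cat29 <- drug_catalog()
  arch <- drug_archetypes(4, g, seed = 5)
  prof <- manufacturer_profiles(arch, cat29, manufacturer_effect = 0.3,
                                seed = 5)
  curves <- t(vapply(prof, profile_curve, numeric(g$n_channels), grid = g))
  cossim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  drugs <- cat29$drug_id
  within <- c(); across <- c()
  for (i in 1:28) for (j in (i + 1):29) {
    s <- cossim(curves[i, ], curves[j, ])
    if (drugs[i] == drugs[j]) within <- c(within, s) else across <- c(across, s)
  }
  expect_gt(mean(within), mean(across))
})

test_that("generated datasets honor catalog counts, seeds and noise", {
  g <- tiny_grid()
  cat4 <- tiny_catalog()
  ds <- simulate_dataset(cat4, g, seed = 11)
  expect_equal(nrow(ds$x), sum(cat4$n_samples))
  expect_equal(as.vector(table(ds$class_id)), cat4$n_samples)
  expect_identical(simulate_dataset(cat4, g, seed = 11)$x, ds$x)
  expect_false(identical(simulate_dataset(cat4, g, seed = 12)$x, ds$x))
  # bundled catalog gives the full 1721 spectra
  big <- simulate_dataset(grid = tiny_grid(16), seed = 1)
  expect_equal(nrow(big$x), 1721L)
  expect_equal(as.vector(table(big$class_id)), drug_catalog()$n_samples)
})

test_that("all dispersion at zero makes class spectra identical", {
  g <- tiny_grid()
  arch <- drug_archetypes(2, g, seed = 2)
  cat4 <- tiny_catalog()
  prof <- manufacturer_profiles(arch, cat4, 0, seed = 1)
  ds <- simulate_spectra(prof, cat4, noise_sd = 0, scatter_sd = 0,
                         drift_sd = 0, tilt_sd = 0, outlier_prob = 0,
                         grid = g, seed = 1)
  rows <- which(ds$class_id == 1)
  expect_true(all(apply(ds$x[rows, ], 2, function(col) diff(range(col)) == 0)))
  # with zero manufacturer effect the whole drug family is constant
  fam <- which(ds$drug_id == 1)
  expect_true(all(apply(ds$x[fam, ], 2, function(col) diff(range(col)) == 0)))
})

test_that("additive channel noise has the requested standard deviation", {
  g <- tiny_grid(32)
  cat1 <- class_catalog(1, 1, 400)
  arch <- drug_archetypes(1, g, seed = 4)
  prof <- manufacturer_profiles(arch, cat1, 0, seed = 4)
  ds <- simulate_spectra(prof, cat1, noise_sd = 0.05, scatter_sd = 0,
                         drift_sd = 0, tilt_sd = 0, outlier_prob = 0,
                         grid = g, seed = 8)
  sds <- apply(ds$x, 2, sd)
  expect_lt(abs(mean(sds) - 0.05) / 0.05, 0.1)
})
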