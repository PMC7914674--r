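# nirbigan

Multi-class drug identification from near-infrared (NIR) spectra with a
modified bidirectional generative adversarial network (Bi-GAN).

## The problem

Drug surveillance labs need to tell not only *which* drug a tablet is but
*which manufacturer* produced it, from a single non-destructive NIR scan.
Same-drug products from different manufacturers have nearly identical
spectra, sample collections are strongly imbalanced (a few manufacturers
contribute over a hundred spectra, many contribute a couple of dozen), and
misclassifying a common product as a rare one is costly. Classical
chemometric classifiers (PLS-DA, SVMs, k-NN) degrade in exactly this
regime.

`nirbigan` implements a generative approach for this setting. A
bidirectional GAN learns an encoder `E : x -> z` (spectrum to a 30-dim
latent code), a generator `G : z -> x` and a discriminator `D(x, z)` that
is trained to tell real couples `(x, E(x))` from generated couples
`(G(z), z)`. Three modifications adapt it to class-targeted generation:

1. **Template-conditioned latent prior.** Latent codes are drawn from
   `N(E(x_i), diag(sigma^2))` around the encoding of a real template
   spectrum `x_i`; `sigma` starts at 1 and adapts elementwise from the
   spread of the last five encodings (per class),
   `sigma_d = sqrt( sum_j (h_jd - mu_d)^2 / 4 )`.
2. **Classification-augmented adversarial losses.** A softmax classifier
   `C` (pre-trained on real spectra) scores generated samples against
   their template's label; its cross-entropy is added to both the
   discriminator loss
   `-sum_i [ y_i log D_i + (1-y_i) log(1-D_i) ] + L_cls`
   and the generator/encoder loss `-sum_i log D_i + L_cls`, so class
   supervision runs through all of training.
3. **Balanced resampling and majority-vote inference.** Every class
   contributes an equal number of with-replacement draws per epoch, and a
   deployed prediction encodes the query, draws `r` latent codes from the
   conditioned prior, generates and classifies each, and returns the modal
   class (ties to the lowest class id).

Because the 1721-spectrum, 29-manufacturer, 4-drug reference collection is
not publicly deposited, the package ships a synthetic spectra generator
with the same catalog structure (Gaussian absorbance bands per drug
family, bounded manufacturer perturbations, EMSC-style per-spectrum
scatter/drift nuisance with occasional outlier measurements, additive
channel noise), so every part of the pipeline is testable end to end.

## Worked example

```r
library(nirbigan)

grid <- wavenumber_grid(n_channels = 512)         # 4000-11995 cm^-1
ds   <- simulate_dataset(grid = grid, seed = 11)  # 1721 spectra, 29 classes
ds
#> Spectral dataset: 1721 spectra x 512 channels, 29 classes, 4 drug families
#> Wavenumber grid: 4000.00-11995.00 cm^-1, 512 channels (spacing 15.646 cm^-1)

split <- stratified_split(ds, 0.9, seed = 101)
fit   <- bigan(ds, split = split, config = bigan_config(grid = grid), seed = 7)
fit
#> Modified Bi-GAN NIR classifier
#>   input: 512 channels (4000-11995 cm^-1), latent dim 30, 29 classes
#>   state: trained

te   <- split_indices(split, "test")
pred <- predict(fit, ds[te], seed = 9)
eval_report(ds$class_id[te], pred, 29, split_fraction = 0.9)
#> Evaluation report (n = 173, train fraction 0.90):
#>   accuracy 0.7399 | macro precision 0.6996 | macro recall 0.6927 | F1 0.6961
```

The accuracy line is the majority-vote test accuracy over the untouched
10% test partition (173 spectra); precision/recall/F1 are macro-averaged
over the 29 classes. On this calibrated synthetic regime (chosen so a
1-nearest-neighbour baseline lands near 0.90, the difficulty band reported
for real NIR drug collections) the adversarially trained pipeline reaches
about 0.6-0.8; the methods vignette discusses why the generative chain
tracks below 1-NN here and on what kind of data it does not.

A vote table with per-class counts is available via
`predict(fit, ds[te], type = "votes")`, class-conditioned synthetic
spectra via `simulate(fit, nsim = 10, template = ds$x[1, ])`, and the
classical baselines via e.g.

```r
b <- fit_baseline(baseline_model("knn"), ds$x[split_indices(split, "train"), ],
                  ds$class_id[split_indices(split, "train")], k = 29)
mean(predict(b, ds$x[te, ]) == ds$class_id[te])
#> [1] 0.8959538
```

`run_benchmark()` sweeps train:test ratios 9:1 ... 2:8 with repeated
splits and best-of-N plus mean±sd summaries. A command-line interface
(`inst/cli/nirbigan.R`) exposes `simulate`, `train`, `predict`, `evaluate`
and `benchmark` subcommands over the same functions.

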