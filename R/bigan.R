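#' Bi-GAN configuration
#'
#' Collects every tunable of the modified Bi-GAN. Defaults reproduce the
#' reference configuration: 2074 input channels, latent dimension 30,
#' encoder 2074-120-30 (ReLU; dropout 0.2 before and batch normalization
#' after each dense layer), generator 30-360-2074 (ReLU hidden, linear
#' output), classifier 2074-150-k (sigmoid hidden, softmax output),
#' discriminator on the concatenated (spectrum, latent) couple
#' 2104-120-1 (ReLU hidden, sigmoid output), RMSprop with Keras default
#' parameters, batch size 60, 150 adversarial epochs.
#'
#' @param grid [wavenumber_grid()] fixing the input width.
#' @param latent_dim Latent dimension (encoder output / generator input).
#' @param encoder_hidden,generator_hidden,discriminator_hidden,classifier_hidden
#'   Hidden-layer widths.
#' @param dropout Dropout rate in the encoder (default 0.2).
#' @param batch_size Minibatch size (default 60).
#' @param epochs Adversarial training epochs (default 150).
#' @param pretrain_epochs Classifier pre-training epochs (default 150).
#' @param n_per_class Balanced-resampling draws per class and epoch
#'   (default 60).
#' @param learning_rate,rmsprop_rho,rmsprop_eps RMSprop hyperparameters
#'   (Keras defaults).
#' @param sigma_floor Lower bound on the latent prior scale.
#' @param history_depth Encoding history depth of the prior (default 5).
#' @param per_class_history Keep one encoding history per class instead of
#'   a single global FIFO (default `TRUE`; the global variant lets the
#'   prior scale track between-class encoding distances, which scrambles
#'   class identity in the latent codes).
#' @param classifier_real_refresh Also include the real template spectra
#'   (with their true labels) in the classifier's formal-training step, in
#'   equal number to the generated spectra (default `TRUE`). Without the
#'   refresh the classifier is optimized on generated samples alone and
#'   catastrophically forgets its pre-trained knowledge of real spectra
#'   while the generator is still immature, collapsing the class anchor of
#'   the whole loop; `FALSE` gives that generated-only behaviour.
#' @param encoder_train_mode Run the encoder's forward passes inside the
#'   training loop in training mode — dropout masks active, batch-statistic
#'   normalization — as a combined Keras-style graph would (default
#'   `TRUE`). With `FALSE` the encoder runs in evaluation mode inside the
#'   loop (batch-norm running statistics refreshed from the training data
#'   each epoch); that variant gives crisper priors but is prone to a
#'   latent-scale feedback collapse on many-class data.
#' @param predict_sigma Elementwise prior scale used at inference:
#'   `"auto"` (default) uses the per-dimension median of the trained
#'   per-class prior scales — the adapted diversity the prior learned —
#'   or a fixed scalar/vector.
#' @param repeats Majority-vote repeats at inference (default 15, odd to
#'   reduce ties).
#' @param eps_log Log-clipping constant inside cross-entropies.
#' @return A list of class `"bigan_config"`.
#' @export
bigan_config <- function(grid = wavenumber_grid(), latent_dim = 30L,
                         encoder_hidden = 120L, generator_hidden = 360L,
                         discriminator_hidden = 120L,
                         classifier_hidden = 150L, dropout = 0.2,
                         batch_size = 60L, epochs = 150L,
                         pretrain_epochs = 150L, n_per_class = 60L,
                         learning_rate = 1e-3, rmsprop_rho = 0.9,
                         rmsprop_eps = 1e-7, sigma_floor = 1e-6,
                         history_depth = 5L, per_class_history = TRUE,
                         classifier_real_refresh = TRUE,
                         encoder_train_mode = TRUE,
                         predict_sigma = "auto", repeats = 15L,
                         eps_log = 1e-7) {
  stopifnot(inherits(grid, "wavenumber_grid"), latent_dim >= 1L,
            batch_size >= 1L, epochs >= 0L, pretrain_epochs >= 0L,
            n_per_class >= 1L, dropout >= 0, dropout < 1,
            sigma_floor > 0, history_depth >= 2L, repeats >= 1L)
  structure(list(grid = grid, latent_dim = as.integer(latent_dim),
                 encoder_hidden = as.integer(encoder_hidden),
                 generator_hidden = as.integer(generator_hidden),
                 discriminator_hidden = as.integer(discriminator_hidden),
                 classifier_hidden = as.integer(classifier_hidden),
                 dropout = dropout, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 n_per_class = as.integer(n_per_class),
                 learning_rate = learning_rate, rmsprop_rho = rmsprop_rho,
                 rmsprop_eps = rmsprop_eps, sigma_floor = sigma_floor,
                 history_depth = as.integer(history_depth),
                 per_class_history = isTRUE(per_class_history),
                 classifier_real_refresh = isTRUE(classifier_real_refresh),
                 encoder_train_mode = isTRUE(encoder_train_mode),
                 predict_sigma = predict_sigma, repeats = as.integer(repeats),
                 eps_log = eps_log),
            class = "bigan_config")
}

#' Build an untrained Bi-GAN model
#'
#' Initializes the four networks (encoder E, generator G, discriminator D,
#' classifier C) for a catalog of k classes under a configuration.
#' Initialization is Glorot-uniform and deterministic under `seed`.
#'
#' @param catalog A `"class_catalog"` with k >= 2 classes.
#' @param config A [bigan_config()].
#' @param seed Integer seed.
#' @return An object of class `"bigan"` (untrained).
#' @export
build_bigan <- function(catalog, config = bigan_config(), seed = 1L) {
  stopifnot(inherits(catalog, "class_catalog"), inherits(config, "bigan_config"))
  k <- nrow(catalog)
  if (k < 2L) stop("need at least 2 classes")
  L <- config$grid$n_channels
  d <- config$latent_dim
  set.seed(as.integer(seed))
  E <- mlp_new(c(L, config$encoder_hidden, d),
               acts = c(rep("relu", length(config$encoder_hidden)), "linear"),
               dropout = rep(config$dropout, length(config$encoder_hidden) + 1L),
               bn = rep(TRUE, length(config$encoder_hidden) + 1L))
  G <- mlp_new(c(d, config$generator_hidden, L),
               acts = c(rep("relu", length(config$generator_hidden)), "linear"))
  D <- mlp_new(c(L + d, config$discriminator_hidden, 1L),
               acts = c(rep("relu", length(config$discriminator_hidden)), "sigmoid"))
  C <- mlp_new(c(L, config$classifier_hidden, k),
               acts = c(rep("sigmoid", length(config$classifier_hidden)), "softmax"))
  structure(list(networks = list(E = E, G = G, D = D, C = C),
                 opt = list(E = rmsprop_state(E), G = rmsprop_state(G),
                            D = rmsprop_state(D), C = rmsprop_state(C)),
                 config = config, catalog = catalog, k = k,
                 scaling = NULL, trained = FALSE, pretrained = FALSE,
                 trace = NULL, pretrain_trace = NULL, prior = NULL),
            class = "bigan")
}

# ---- preprocessing -------------------------------------------------------

# Global min-max scaling to [0, 1], fit on the training partition and
# stored with the model so the inverse transform is exact.
fit_scaling <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) hi <- lo + 1
  list(min = lo, max = hi)
}

scale_spectra <- function(x, scaling) {
  if (is.null(scaling)) return(x)
  (x - scaling$min) / (scaling$max - scaling$min)
}

unscale_spectra <- function(x, scaling) {
  if (is.null(scaling)) return(x)
  x * (scaling$max - scaling$min) + scaling$min
}

.as_row_matrix <- function(x, width, what) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != width)
    stop(what, " must have ", width, " columns, got ", ncol(x))
  if (anyNA(x) || !all(is.finite(x))) stop(what, " must be finite")
  x
}

.onehot <- function(labels, k) {
  out <- matrix(0, length(labels), k)
  out[cbind(seq_along(labels), labels)] <- 1
  out
}

# ---- network accessors ---------------------------------------------------

#' Encode spectra into the latent space
#'
#' Applies the model's stored min-max scaling and the encoder E in
#' evaluation mode (dropout off, batch normalization on running
#' statistics), so identical inputs give identical encodings.
#'
#' @param model A `"bigan"`.
#' @param x Spectrum vector or matrix (rows = spectra) on the raw
#'   absorbance scale.
#' @return Matrix of encodings (rows = spectra, `latent_dim` columns); a
#'   single input vector yields a 1-row matrix.
#' @export
encode <- function(model, x) {
  stopifnot(inherits(model, "bigan"))
  x <- .as_row_matrix(x, model$config$grid$n_channels, "spectra")
  mlp_forward(model$networks$E, scale_spectra(x, model$scaling))$out
}

#' Generate spectra from latent codes
#'
#' Runs the generator G on latent vectors and maps the output back to the
#' raw absorbance scale through the stored inverse scaling.
#'
#' @param model A `"bigan"`.
#' @param z Latent vector or matrix (rows = codes, `latent_dim` columns).
#' @return Matrix of spectra (rows = spectra).
#' @export
generate_spectra <- function(model, z) {
  stopifnot(inherits(model, "bigan"))
  z <- .as_row_matrix(z, model$config$latent_dim, "latent codes")
  unscale_spectra(mlp_forward(model$networks$G, z)$out, model$scaling)
}

#' Discriminate a (spectrum, latent) couple
#'
#' Probability, under the discriminator D, that the couple is a real
#' spectrum paired with its own encoding (source label y = 1) rather than
#' a generated spectrum paired with its latent code (y = 0).
#'
#' @param model A `"bigan"`.
#' @param x Spectrum vector or matrix (raw absorbance scale).
#' @param z Latent vector or matrix, conformable with `x`.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
discriminate <- function(model, x, z) {
  stopifnot(inherits(model, "bigan"))
  x <- .as_row_matrix(x, model$config$grid$n_channels, "spectra")
  z <- .as_row_matrix(z, model$config$latent_dim, "latent codes")
  if (nrow(x) != nrow(z)) stop("'x' and 'z' must have the same number of rows")
  couple <- cbind(scale_spectra(x, model$scaling), z)
  drop(mlp_forward(model$networks$D, couple)$out)
}

#' Classify spectra with the softmax classifier
#'
#' @param model A `"bigan"`.
#' @param x Spectrum vector or matrix (raw absorbance scale).
#' @return Matrix of class probabilities (rows sum to 1).
#' @export
classify <- function(model, x) {
  stopifnot(inherits(model, "bigan"))
  x <- .as_row_matrix(x, model$config$grid$n_channels, "spectra")
  mlp_forward(model$networks$C, scale_spectra(x, model$scaling))$out
}

# ---- training ------------------------------------------------------------

# Balanced with-replacement draw using the current RNG stream.
.balanced_draw <- function(split, n_per_class) {
  cls <- names(split$train)[order(as.integer(names(split$train)))]
  unlist(lapply(cls, function(c_id) {
    pool <- split$train[[c_id]]
    pool[sample.int(length(pool), n_per_class, replace = TRUE)]
  }), use.names = FALSE)
}

.clip01 <- function(p, eps) pmin(pmax(p, eps), 1 - eps)

#' Pre-train the classifier on real spectra
#'
#' Optimizes the classifier C alone, by RMSprop on the summed cross-entropy
#' against true labels, using balanced with-replacement resampling of the
#' training partition so every class contributes equally. The encoder,
#' generator and discriminator are untouched. Called automatically by
#' [bigan()]; exposed for staged training.
#'
#' @param model A `"bigan"` with scaling fitted (or it is fitted here from
#'   the training partition).
#' @param dataset A [spectral_dataset()].
#' @param split A `"split_plan"` on `dataset`.
#' @param epochs Number of passes (default from the model config); 0 leaves
#'   the classifier unchanged.
#' @param seed Integer seed.
#' @return The model with updated classifier and a `pretrain_trace`
#'   data.frame (epoch, loss, accuracy on the resampled pool).
#' @export
pretrain_classifier <- function(model, dataset, split,
                                epochs = model$config$pretrain_epochs,
                                seed = 1L) {
  stopifnot(inherits(model, "bigan"), inherits(dataset, "spectral_dataset"),
            inherits(split, "split_plan"))
  cfg <- model$config
  if (is.null(model$scaling))
    model$scaling <- fit_scaling(dataset$x[split_indices(split, "train"), ])
  if (epochs == 0L) { model$pretrained <- TRUE; return(model) }
  miss <- setdiff(model$catalog$class_id, as.integer(names(split$train)))
  if (length(miss))
    stop("training pool is missing class(es): ", paste(miss, collapse = ", "))
  xs <- scale_spectra(dataset$x, model$scaling)
  k <- model$k
  Cn <- model$networks$C
  stC <- model$opt$C
  set.seed(as.integer(seed))
  trace <- data.frame(epoch = seq_len(epochs), loss = NA_real_,
                      accuracy = NA_real_)
  for (ep in seq_len(epochs)) {
    pool <- .balanced_draw(split, cfg$n_per_class)
    pool <- pool[sample.int(length(pool))]
    tot_loss <- 0; tot_ok <- 0L
    for (bi in split(pool, ceiling(seq_along(pool) / cfg$batch_size))) {
      X <- xs[bi, , drop = FALSE]
      Y <- .onehot(dataset$class_id[bi], k)
      fc <- mlp_forward(Cn, X, training = TRUE)
      tot_loss <- tot_loss + loss_classification(Y, fc$out, cfg$eps_log)
      tot_ok <- tot_ok + sum(max.col(fc$out, ties.method = "first") ==
                               dataset$class_id[bi])
      dA <- -(Y / pmax(fc$out, cfg$eps_log))
      bk <- mlp_backward(fc$net, fc$cache, dA)
      st <- rmsprop_step(fc$net, bk$grads, stC, lr = cfg$learning_rate,
                         rho = cfg$rmsprop_rho, eps = cfg$rmsprop_eps)
      Cn <- st$net; stC <- st$state
    }
    trace$loss[ep] <- tot_loss / length(pool)
    trace$accuracy[ep] <- tot_ok / length(pool)
  }
  model$networks$C <- Cn
  model$opt$C <- stC
  model$pretrain_trace <- trace
  model$pretrained <- TRUE
  model
}

#' Adversarial training of the modified Bi-GAN
#'
#' Alternating optimization. Per minibatch of balanced resampled template
#' spectra:
#' 1. the templates are encoded in training mode (dropout and batch
#'    statistics active);
#' 2. the conditioned latent prior is updated with each encoding in stream
#'    order and a latent code is drawn per template by the
#'    reparameterization `z = E(x) + sigma * eps`;
#' 3. the generator produces synthetic spectra `G(z)`;
#' 4. discriminator step: minimize the binary cross-entropy on real couples
#'    `(x, E(x))` (label 1) versus generated couples `(G(z), z)` (label 0),
#'    with the classification loss of the generated batch added to the
#'    reported loss;
#' 5. generator/encoder step: minimize `-sum(log D(G(z), z))` plus the
#'    classification loss of `C(G(z))` against the template labels, with
#'    gradients flowing into G through the spectrum arm and into E through
#'    the latent arm of the couple;
#' 6. classifier step: minimize the cross-entropy of `C(G(z))` against the
#'    template labels (generated samples only — real spectra are used only
#'    in pre-training).
#'
#' @param model A pre-trained `"bigan"` (see [pretrain_classifier()]).
#' @param dataset A [spectral_dataset()].
#' @param split A `"split_plan"`; only its training partition is touched.
#' @param epochs Adversarial epochs (default from the config).
#' @param seed Integer seed.
#' @return The trained model, with a `trace` data.frame holding per-epoch
#'   mean discriminator, generator and classifier losses.
#' @export
train_bigan <- function(model, dataset, split,
                        epochs = model$config$epochs, seed = 1L) {
  stopifnot(inherits(model, "bigan"), inherits(dataset, "spectral_dataset"),
            inherits(split, "split_plan"))
  if (!isTRUE(model$pretrained))
    stop("classifier must be pre-trained first; see pretrain_classifier()")
  cfg <- model$config
  L <- cfg$grid$n_channels
  d <- cfg$latent_dim
  k <- model$k
  xs <- scale_spectra(dataset$x, model$scaling)
  E <- model$networks$E; G <- model$networks$G
  D <- model$networks$D; Cn <- model$networks$C
  stE <- model$opt$E; stG <- model$opt$G; stD <- model$opt$D; stC <- model$opt$C
  new_prior <- function() latent_prior(d, sigma_floor = cfg$sigma_floor,
                                       history_depth = cfg$history_depth)
  priors <- if (cfg$per_class_history)
    setNames(replicate(k, new_prior(), simplify = FALSE),
             as.character(model$catalog$class_id))
  else new_prior()
  set.seed(as.integer(seed))
  trace <- data.frame(epoch = integer(0), d_loss = numeric(0),
                      g_loss = numeric(0), c_loss = numeric(0))
  xtrain <- xs[split_indices(split, "train"), , drop = FALSE]
  for (ep in seq_len(epochs)) {
    if (!cfg$encoder_train_mode)
      E <- mlp_refresh_bn(E, xtrain)
    pool <- .balanced_draw(split, cfg$n_per_class)
    pool <- pool[sample.int(length(pool))]
    eL <- c(d = 0, g = 0, c = 0); nb_count <- 0L
    for (bi in split(pool, ceiling(seq_along(pool) / cfg$batch_size))) {
      nb <- length(bi)
      X <- xs[bi, , drop = FALSE]
      labels <- dataset$class_id[bi]
      Y1 <- .onehot(labels, k)

      fE <- mlp_forward(E, X, training = cfg$encoder_train_mode)
      E <- fE$net
      Enc <- fE$out
      Sig <- matrix(0, nb, d)
      for (i in seq_len(nb)) {
        if (cfg$per_class_history) {
          key <- as.character(labels[i])
          priors[[key]] <- update_prior(priors[[key]], Enc[i, ])
          Sig[i, ] <- priors[[key]]$sigma
        } else {
          priors <- update_prior(priors, Enc[i, ])
          Sig[i, ] <- priors$sigma
        }
      }
      Z <- Enc + Sig * matrix(stats::rnorm(nb * d), nb)
      fG <- mlp_forward(G, Z, training = TRUE)
      Xg <- fG$out

      # discriminator step
      couples <- rbind(cbind(X, Enc), cbind(Xg, Z))
      ysrc <- rep(c(1, 0), each = nb)
      fD <- mlp_forward(D, couples, training = TRUE)
      yh <- drop(fD$out)
      cls_now <- loss_classification(Y1, mlp_forward(Cn, Xg)$out, cfg$eps_log)
      eL["d"] <- eL["d"] + loss_discriminator(ysrc, yh, cls_now, cfg$eps_log)
      p <- .clip01(yh, cfg$eps_log)
      dyh <- -(ysrc / p - (1 - ysrc) / (1 - p))
      bD <- mlp_backward(fD$net, fD$cache, matrix(dyh, ncol = 1L))
      st <- rmsprop_step(fD$net, bD$grads, stD, lr = cfg$learning_rate,
                         rho = cfg$rmsprop_rho, eps = cfg$rmsprop_eps)
      D <- st$net; stD <- st$state

      # generator + encoder step (through the updated discriminator)
      fD2 <- mlp_forward(D, cbind(Xg, Z), training = TRUE)
      yh2 <- drop(fD2$out)
      fC2 <- mlp_forward(Cn, Xg, training = TRUE)
      cls_g <- loss_classification(Y1, fC2$out, cfg$eps_log)
      eL["g"] <- eL["g"] + loss_generator(yh2, cls_g, cfg$eps_log)
      dyh2 <- matrix(-1 / .clip01(yh2, cfg$eps_log), ncol = 1L)
      bD2 <- mlp_backward(fD2$net, fD2$cache, dyh2)
      bC2 <- mlp_backward(fC2$net, fC2$cache,
                          -(Y1 / pmax(fC2$out, cfg$eps_log)))
      dXg <- bD2$dX[, seq_len(L), drop = FALSE] + bC2$dX
      bG <- mlp_backward(fG$net, fG$cache, dXg)
      dZ <- bD2$dX[, L + seq_len(d), drop = FALSE] + bG$dX
      st <- rmsprop_step(fG$net, bG$grads, stG, lr = cfg$learning_rate,
                         rho = cfg$rmsprop_rho, eps = cfg$rmsprop_eps)
      G <- st$net; stG <- st$state
      bE <- mlp_backward(fE$net, fE$cache, dZ)  # dz/dE(x) = identity
      st <- rmsprop_step(fE$net, bE$grads, stE, lr = cfg$learning_rate,
                         rho = cfg$rmsprop_rho, eps = cfg$rmsprop_eps)
      E <- st$net; stE <- st$state

      # classifier step on generated samples, with the real templates mixed
      # in (equal parts) unless the generated-only variant is requested
      if (cfg$classifier_real_refresh) {
        Xc <- rbind(Xg, X)
        Yc <- rbind(Y1, Y1)
      } else {
        Xc <- Xg
        Yc <- Y1
      }
      fC3 <- mlp_forward(Cn, Xc, training = TRUE)
      eL["c"] <- eL["c"] + loss_classification(Yc, fC3$out, cfg$eps_log) *
        nrow(Y1) / nrow(Yc)
      bC3 <- mlp_backward(fC3$net, fC3$cache,
                          -(Yc / pmax(fC3$out, cfg$eps_log)))
      st <- rmsprop_step(fC3$net, bC3$grads, stC, lr = cfg$learning_rate,
                         rho = cfg$rmsprop_rho, eps = cfg$rmsprop_eps)
      Cn <- st$net; stC <- st$state
      nb_count <- nb_count + 1L
    }
    if (!all(is.finite(eL)))
      stop(sprintf(paste0("training diverged at epoch %d ",
                          "(d=%.3g, g=%.3g, c=%.3g); try a lower learning ",
                          "rate or fewer epochs"), ep, eL["d"], eL["g"],
                   eL["c"]))
    trace <- rbind(trace, data.frame(epoch = ep, d_loss = eL["d"] / nb_count,
                                     g_loss = eL["g"] / nb_count,
                                     c_loss = eL["c"] / nb_count))
  }
  rownames(trace) <- NULL
  model$networks <- list(E = E, G = G, D = D, C = Cn)
  model$opt <- list(E = stE, G = stG, D = stD, C = stC)
  model$trace <- trace
  model$prior <- priors
  # adapted inference-time prior scale: the per-dimension median of the
  # trained class priors (a single prior's scale when the history is global)
  model$inference_sigma <- if (cfg$per_class_history)
    apply(vapply(priors, function(p) p$sigma, numeric(d)), 1L, stats::median)
  else priors$sigma
  model$trained <- TRUE
  model
}

#' Fit the modified Bi-GAN classifier
#'
#' One-call fit: stratified split (unless one is supplied), min-max scaling
#' from the training partition, network initialization, classifier
#' pre-training on real spectra and adversarial training of the four
#' networks. All stages draw their seeds from named substreams of the
#' single `seed` (see [substream_seed()]), so the fit is bit-reproducible.
#'
#' @param dataset A [spectral_dataset()] whose grid matches `config$grid`.
#' @param train_fraction Train fraction used when `split` is `NULL`
#'   (default 0.9).
#' @param split Optional `"split_plan"` overriding `train_fraction`.
#' @param config A [bigan_config()]; defaults to the reference
#'   configuration on the dataset's grid.
#' @param seed Master seed (default 1).
#' @return A trained object of class `"bigan"` with the split stored in
#'   `$split`.
#' @examples
#' \donttest{
#' ds <- simulate_dataset(grid = wavenumber_grid(n_channels = 128), seed = 3)
#' cfg <- bigan_config(grid = ds$grid, epochs = 5, pretrain_epochs = 5,
#'                     n_per_class = 10)
#' fit <- bigan(ds, config = cfg, seed = 3)
#' fit
#' }
#' @export
bigan <- function(dataset, train_fraction = 0.9, split = NULL,
                  config = bigan_config(grid = dataset$grid), seed = 1L) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  if (dataset$grid$n_channels != config$grid$n_channels)
    stop("dataset grid and config grid disagree on channel count")
  if (is.null(split))
    split <- stratified_split(dataset, train_fraction,
                              seed = substream_seed(seed, "split"))
  catalog <- dataset$catalog
  if (is.null(catalog)) {
    sizes <- table(dataset$class_id)
    catalog <- class_catalog(as.integer(names(sizes)),
                             vapply(as.integer(names(sizes)), function(cc)
                               dataset$drug_id[match(cc, dataset$class_id)],
                               integer(1)),
                             as.integer(sizes))
  }
  model <- build_bigan(catalog, config, seed = substream_seed(seed, "init"))
  model$scaling <- fit_scaling(dataset$x[split_indices(split, "train"), ])
  model <- pretrain_classifier(model, dataset, split,
                               seed = substream_seed(seed, "pretrain"))
  model <- train_bigan(model, dataset, split,
                       seed = substream_seed(seed, "train"))
  model$split <- split
  model$seed <- as.integer(seed)
  model
}
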