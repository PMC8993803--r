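# DCGAN-style generator/discriminator for synthesizing scarce abnormality
# classes. The generator projects a 100-dimensional Gaussian noise vector to
# a 4x4 feature block, then climbs a stride-2 fractionally-strided
# convolution ladder (batch-norm + ReLU, tanh output without batch-norm) to
# the configured power-of-two image size. The discriminator descends the
# mirrored stride-2 convolution ladder (batch-norm + leaky ReLU) to a single
# sigmoid unit. Images cross the module boundary in [0, 1] and are mapped
# to/from the generator's [-1, 1] tanh range internally.

#' GAN architecture specification
#'
#' @param noise_dim Noise vector dimensionality (default 100).
#' @param gen_filters Generator filter ladder from the 4x4 projection
#'   upward; at least `log2(output_size/4)` entries are used.
#' @param disc_filters Discriminator filter ladder.
#' @param kernel_size Convolution kernel side (5).
#' @param output_size Output image side; a power of two reachable from 4x4
#'   by stride-2 upsampling (default 256).
#' @return A `gan_spec` list.
#' @export
gan_spec <- function(noise_dim = 100L,
                     gen_filters = c(1024L, 512L, 256L, 128L, 64L, 32L),
                     disc_filters = c(64L, 128L, 256L, 512L, 1024L),
                     kernel_size = 5L, output_size = 256L) {
  stopifnot(noise_dim >= 1, output_size >= 8)
  n_up <- log2(output_size / 4)
  if (n_up != round(n_up)) {
    stop("output_size must be a power of two reachable from 4x4")
  }
  if (length(gen_filters) < n_up) {
    stop(sprintf("gen_filters needs at least %d entries for output_size %d",
                 n_up, output_size))
  }
  if (length(disc_filters) < n_up) {
    stop(sprintf("disc_filters needs at least %d entries for output_size %d",
                 n_up, output_size))
  }
  structure(list(noise_dim = as.integer(noise_dim),
                 gen_filters = as.integer(gen_filters),
                 disc_filters = as.integer(disc_filters),
                 kernel_size = as.integer(kernel_size),
                 output_size = as.integer(output_size),
                 output_channels = 1L, n_up = as.integer(n_up)),
            class = "gan_spec")
}

#' GAN training configuration
#'
#' Canonical training defaults: minibatch 32, Adam with
#' generator rate 1e-5 and discriminator rate 1e-4, beta1 = 0.5,
#' beta2 = 0.999.
#'
#' @param batch_size Minibatch size (>= 2).
#' @param gen_lr,disc_lr Adam learning rates.
#' @param beta1,beta2 Adam moment decay rates.
#' @param steps Number of alternating update steps.
#' @param seed Integer seed.
#' @return A `gan_train_config` list.
#' @export
gan_train_config <- function(batch_size = 32L, gen_lr = 1e-5, disc_lr = 1e-4,
                             beta1 = 0.5, beta2 = 0.999, steps = 100L,
                             seed = 1L) {
  stopifnot(batch_size >= 2, gen_lr > 0, disc_lr > 0, steps >= 1)
  structure(list(batch_size = as.integer(batch_size), gen_lr = gen_lr,
                 disc_lr = disc_lr, beta1 = beta1, beta2 = beta2,
                 steps = as.integer(steps), seed = as.integer(seed)),
            class = "gan_train_config")
}

#' Build the DCGAN generator
#'
#' Dense projection of the noise batch to `4 x 4 x gen_filters[1]` with
#' batch-norm + ReLU, then stride-2 transposed convolutions
#' (batch-norm + ReLU) up the filter ladder, and a final transposed
#' convolution to one channel with tanh and no batch-norm. Weights use the
#' normal(0, 0.02) initializer.
#'
#' @param spec A [gan_spec()].
#' @return An `nn_model` mapping `(noise_dim, N)` noise matrices to
#'   `(size, size, 1, N)` image batches in \[-1, 1\].
#' @export
build_generator <- function(spec = gan_spec()) {
  gf <- spec$gen_filters
  k <- spec$kernel_size
  layers <- list(ly_dense(spec$noise_dim, 4 * 4 * gf[1], init_sd = 0.02),
                 ly_reshape(c(4L, 4L, gf[1])),
                 ly_batchnorm(gf[1]), ly_act(relu_activation()))
  side <- 4L; cin <- gf[1]
  for (u in seq_len(spec$n_up)) {
    last <- u == spec$n_up
    cout <- if (last) spec$output_channels else gf[u + 1]
    layers <- c(layers, list(ly_convtr(k, cin, cout, out_h = side * 2L,
                                       out_w = side * 2L)))
    if (!last) {
      layers <- c(layers, list(ly_batchnorm(cout), ly_act(relu_activation())))
    } else {
      layers <- c(layers, list(ly_act(tanh_activation())))
    }
    side <- side * 2L; cin <- cout
  }
  nn_model(layers, meta = list(spec = spec, kind = "generator"))
}

#' Build the DCGAN discriminator
#'
#' Stride-2 5x5 convolutions with batch-norm + leaky ReLU down to 4x4,
#' then flatten and a single sigmoid unit.
#'
#' @param spec A [gan_spec()].
#' @return An `nn_model` mapping image batches to per-sample scalars in
#'   (0, 1).
#' @export
build_discriminator <- function(spec = gan_spec()) {
  df <- spec$disc_filters
  k <- spec$kernel_size
  layers <- list()
  side <- spec$output_size; cin <- spec$output_channels
  for (u in seq_len(spec$n_up)) {
    cout <- df[u]
    layers <- c(layers, list(ly_conv(k, cin, cout, stride = 2L,
                                     pad = (k - 1L) %/% 2L, init_sd = 0.02),
                             ly_batchnorm(cout),
                             ly_act(leaky_relu_activation(0.2))))
    side <- side %/% 2L; cin <- cout
  }
  layers <- c(layers, list(ly_flatten(),
                           ly_dense(side^2 * cin, 1L, init_sd = 0.02)))
  nn_model(layers, meta = list(spec = spec, kind = "discriminator"))
}

disc_prob <- function(fw_out) 1 / (1 + exp(-fw_out))

#' Adversarially train a generator/discriminator pair on one class
#'
#' Alternating updates with the standard non-saturating adversarial
#' objective: the discriminator minimizes binary cross-entropy on real vs
#' generated batches, the generator maximizes the discriminator's belief
#' that its samples are real.
#'
#' @param data A `labeled_dataset` restricted to a single class, with at
#'   least `batch_size` images of side `spec$output_size`.
#' @param cfg A [gan_train_config()].
#' @param spec A [gan_spec()].
#' @return A list with `generator`, `discriminator`, and `losses` (a data
#'   frame with per-step discriminator/generator losses, all finite).
#' @export
train_gan <- function(data, cfg = gan_train_config(), spec = gan_spec()) {
  if (length(unique(dataset_labels(data))) != 1) {
    stop("train_gan expects a single-class dataset")
  }
  n <- length(data$samples)
  if (n < cfg$batch_size) {
    stop(sprintf("need at least batch_size = %d images, got %d",
                 cfg$batch_size, n))
  }
  set.seed(cfg$seed)
  gen <- build_generator(spec)
  disc <- build_discriminator(spec)
  size <- spec$output_size
  real <- array(0, c(size, size, 1L, n))
  for (i in seq_len(n)) real[, , 1, i] <- data$samples[[i]]$image * 2 - 1
  gcfg <- list(optimizer = "adam", lr = cfg$gen_lr, beta1 = cfg$beta1,
               beta2 = cfg$beta2)
  dcfg <- list(optimizer = "adam", lr = cfg$disc_lr, beta1 = cfg$beta1,
               beta2 = cfg$beta2)
  bce <- function(p, y) -mean(y * log(pmax(p, 1e-12)) +
                              (1 - y) * log(pmax(1 - p, 1e-12)))
  losses <- data.frame()
  half <- cfg$batch_size %/% 2L
  for (step in seq_len(cfg$steps)) {
    # --- discriminator update on a real half-batch and a fake half-batch
    idx <- sample.int(n, half)
    Z <- matrix(rnorm(spec$noise_dim * half), spec$noise_dim, half)
    fake <- nn_forward(gen, Z, training = TRUE)
    Xb <- array(0, c(size, size, 1L, 2L * half))
    Xb[, , , seq_len(half)] <- real[, , , idx, drop = FALSE]
    Xb[, , , half + seq_len(half)] <- fake$out
    y <- c(rep(1, half), rep(0, half))
    fw <- nn_forward(disc, Xb, training = TRUE)
    p <- as.numeric(disc_prob(fw$out))
    d_loss <- bce(p, y)
    delta <- matrix(p - y, 1) / length(y)          # d BCE / d logit
    nn_update(disc, nn_backward(disc, fw$caches, delta), dcfg)
    # --- generator update: push D(G(z)) toward "real"
    Z <- matrix(rnorm(spec$noise_dim * cfg$batch_size),
                spec$noise_dim, cfg$batch_size)
    fake <- nn_forward(gen, Z, training = TRUE)
    fw <- nn_forward(disc, fake$out, training = TRUE)
    p <- as.numeric(disc_prob(fw$out))
    g_loss <- bce(p, rep(1, length(p)))
    delta <- matrix(p - 1, 1) / length(p)
    grads_d <- nn_backward(disc, fw$caches, delta)
    # gradient w.r.t. the discriminator input = signal into the generator
    dimg <- attr(grads_d, "dX")
    nn_update(gen, nn_backward(gen, fake$caches, dimg), gcfg)
    if (!is.finite(d_loss) || !is.finite(g_loss)) {
      stop(sprintf("non-finite adversarial loss at step %d", step))
    }
    losses <- rbind(losses, data.frame(step = step, d_loss = d_loss,
                                       g_loss = g_loss))
  }
  list(generator = gen, discriminator = disc, losses = losses)
}

#' Sample synthetic images from a trained generator
#'
#' @param gen A generator `nn_model`.
#' @param n Number of samples (>= 1).
#' @param label Class label to tag the samples with.
#' @param seed Integer seed for the noise draws.
#' @param class_set Class set the label belongs to.
#' @param resize_to Optional side length; samples are bilinearly resized.
#' @return A list of [labeled_sample()]s with `source = "gan"` and
#'   intensities in \[0, 1\].
#' @export
synthesize <- function(gen, n, label, seed = 1L,
                       class_set = mammo_classes(extended = TRUE),
                       resize_to = NULL) {
  stopifnot(n >= 1)
  spec <- gen$meta$spec
  set.seed(seed)
  Z <- matrix(rnorm(spec$noise_dim * n), spec$noise_dim, n)
  imgs <- nn_forward(gen, Z, training = FALSE)$out
  lapply(seq_len(n), function(i) {
    img <- (imgs[, , 1, i] + 1) / 2
    img <- pmin(pmax(img, 0), 1)
    if (!is.null(resize_to) && resize_to != nrow(img)) {
      img <- pmin(pmax(as.matrix(EBImage::resize(img, w = resize_to,
                                                 h = resize_to)), 0), 1)
    }
    labeled_sample(img, label, class_set, source = "gan")
  })
}

#' Merge GAN samples into a dataset
#'
#' @param ds A `labeled_dataset`.
#' @param samples A list of `labeled_sample`s (e.g. from [synthesize()]).
#' @return The augmented `labeled_dataset`.
#' @export
augment_dataset <- function(ds, samples) {
  for (s in samples) {
    if (!s$label %in% ds$class_set) {
      stop(sprintf("sample label '%s' outside the dataset class set", s$label))
    }
  }
  ds$samples <- c(ds$samples, samples)
  ds
}
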