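# Independent brute-force oracles used to pin down expected values. These
# are deliberately written as naive double loops / exhaustive enumerations,
# separate from the package's vectorized implementations.

rand_img <- function(n, m = n, seed = 1) {
  set.seed(seed)
  matrix(runif(n * m), n, m)
}

# energy: |dI/dx| + |dI/dy|, central differences with clamped (replicated)
# edge indices, one pixel at a time
oracle_energy <- function(img) {
  n <- nrow(img); m <- ncol(img)
  E <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      jl <- max(1, j - 1); jr <- min(m, j + 1)
      iu <- max(1, i - 1); id <- min(n, i + 1)
      E[i, j] <- abs(img[i, jr] - img[i, jl]) / 2 +
        abs(img[id, j] - img[iu, j]) / 2
    }
  }
  E
}

# exhaustive enumeration of all 8-connected vertical seams; returns the
# minimal total energy
oracle_min_seam_energy <- function(E) {
  n <- nrow(E); m <- ncol(E)
  best <- Inf
  recurse <- function(row, col, acc) {
    acc <- acc + E[row, col]
    if (row == n) {
      if (acc < best) best <<- acc
      return(invisible())
    }
    for (nc in max(1, col - 1):min(m, col + 1)) recurse(row + 1, nc, acc)
  }
  for (start in seq_len(m)) recurse(1, start, 0)
  best
}

# direct 4-tap evaluation of the separable orthonormal Haar products on one
# 2x2 block [[a, b], [c, d]] (rows y, columns x)
oracle_haar_2x2 <- function(a, b, c, d) {
  list(LL = (a + b + c + d) / 2,
       LH = (a - b + c - d) / 2,   # wavelet in x, scaling in y
       HL = (a + b - c - d) / 2,   # scaling in x, wavelet in y
       HH = (a - b - c + d) / 2)
}

# naive per-class one-vs-rest confusion tally
oracle_confusion <- function(y_true, y_pred, classes) {
  out <- matrix(0L, length(classes), 4,
                dimnames = list(classes, c("TP", "TN", "FP", "FN")))
  for (cl in classes) {
    for (i in seq_along(y_true)) {
      t_pos <- y_true[i] == cl
      p_pos <- y_pred[i] == cl
      k <- if (t_pos && p_pos) "TP" else if (!t_pos && !p_pos) "TN"
           else if (!t_pos && p_pos) "FP" else "FN"
      out[cl, k] <- out[cl, k] + 1L
    }
  }
  out
}

# the two-class separable fixture used for learnability checks: masses (M)
# against normals (N) at the generator's default contrast
two_class_data <- function(seed, n_train_per_class = 100,
                           n_val_per_class = 50, size = 64) {
  train <- generate_dataset(synthetic_spec(
    image_size = size, class_counts = c(N = n_train_per_class,
                                        M = n_train_per_class),
    seed = mammowave:::derive_seed(seed, 11), noise_sd = 0.02))
  val <- generate_dataset(synthetic_spec(
    image_size = size, class_counts = c(N = n_val_per_class,
                                        M = n_val_per_class),
    seed = mammowave:::derive_seed(seed, 12), noise_sd = 0.02))
  val$split <- "val"
  train$class_set <- c("N", "M")
  val$class_set <- c("N", "M")
  list(train = train, val = val)
}

# compact wavelet network used for desk-scale training runs
compact_wcnn_spec <- function(input_size = 64, n_classes = 2) {
  network_spec(input_size = input_size, n_blocks = 2L, convs_per_block = 1L,
               filters_per_block = c(16L, 32L), activation = "wavelet",
               n_classes = n_classes, pooling = "avg")
}
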