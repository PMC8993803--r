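# Seeded generator of synthetic mammogram-like images. Backgrounds are smooth
# low-contrast cosine-grating fields with pixel noise; each abnormality class
# adds its characteristic bright structure. Every stage downstream (CLAHE,
# carving, wavelets, networks, GAN, metrics) is testable on these fixtures
# with no external data.

# Deterministic per-sample seed stream: two rounds of a Lehmer step keep all
# intermediates below 2^53 so the arithmetic is exact in doubles.
derive_seed <- function(seed, index) {
  s <- (abs(as.double(seed)) %% 2147483646) + 1
  s <- (s * 16807) %% 2147483647
  s <- ((s + as.double(index)) %% 2147483646) + 1
  as.integer((s * 16807) %% 2147483647)
}

#' Specification of a synthetic mammogram dataset
#'
#' @param image_size Square image side in pixels (default 299, the working
#'   size of the classification networks).
#' @param class_counts Named integer vector, class label to sample count.
#' @param seed Integer seed; identical specs produce bit-identical datasets.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param lesion_intensity Peak additive intensity of the brightest lesion
#'   class, in (0, 1].
#' @param lesion_radius_px Mass radius in pixels; defaults to
#'   `max(3, image_size %/% 12)`.
#' @param class_set Allowed labels; defaults to the five-class set extended
#'   automatically if `class_counts` mentions AD or ASYM.
#' @return A `synthetic_spec` list.
#' @seealso [generate_dataset()], [generate_sample()]
#' @export
synthetic_spec <- function(image_size = 299,
                           class_counts = c(N = 10, BC = 10, BM = 10,
                                            CALC = 10, M = 10),
                           seed = 1L, noise_sd = 0.02,
                           lesion_intensity = 0.5, lesion_radius_px = NULL,
                           class_set = NULL) {
  stopifnot(image_size >= 32, noise_sd >= 0,
            lesion_intensity > 0, lesion_intensity <= 1)
  if (is.null(class_set)) {
    class_set <- mammo_classes(extended = any(names(class_counts) %in%
                                                c("AD", "ASYM")))
  }
  if (length(class_counts) == 0) stop("class_counts must be non-empty")
  if (any(class_counts < 0)) stop("class_counts must be non-negative")
  if (!all(names(class_counts) %in% class_set)) {
    stop("class_counts names must lie within the class set")
  }
  if (is.null(lesion_radius_px)) lesion_radius_px <- max(3L, image_size %/% 12L)
  structure(list(image_size = as.integer(image_size),
                 class_counts = class_counts, seed = as.integer(seed),
                 noise_sd = noise_sd, lesion_intensity = lesion_intensity,
                 lesion_radius_px = as.integer(lesion_radius_px),
                 class_set = class_set),
            class = "synthetic_spec")
}

# Smooth low-contrast background: baseline 0.3 plus 2-3 low-frequency cosine
# gratings of small amplitude, so lesion peaks always clear the background
# maximum by a wide margin.
synth_background <- function(size) {
  xs <- matrix(rep(seq_len(size), each = size), size) / size
  ys <- matrix(rep(seq_len(size), times = size), size) / size
  bg <- matrix(0.3, size, size)
  for (g in seq_len(sample(2:3, 1))) {
    amp <- runif(1, 0.02, 0.035)
    fx <- sample(1:3, 1); fy <- sample(1:3, 1)
    ph <- runif(1, 0, 2 * pi)
    bg <- bg + amp * cos(2 * pi * (fx * xs + fy * ys) + ph)
  }
  bg
}

add_blob <- function(img, cx, cy, radius, amp) {
  n <- nrow(img)
  d2 <- outer(seq_len(n) - cy, seq_len(n) - cx,
              function(i, j) i^2 + j^2)
  img + amp * exp(-d2 / (2 * (radius / 2)^2))
}

add_speckles <- function(img, cx, cy, spread, k, amp) {
  n <- nrow(img)
  for (s in seq_len(k)) {
    px <- max(2L, min(n - 1L, round(cx + rnorm(1, 0, spread))))
    py <- max(2L, min(n - 1L, round(cy + rnorm(1, 0, spread))))
    r <- sample(0:1, 1)                     # speckle diameter 1-3 px
    rows <- max(1L, py - r):min(n, py + r)
    cols <- max(1L, px - r):min(n, px + r)
    img[rows, cols] <- img[rows, cols] + amp
  }
  img
}

add_radial_lines <- function(img, cx, cy, k, len, amp) {
  n <- nrow(img)
  for (s in seq_len(k)) {
    theta <- runif(1, 0, 2 * pi)
    t <- seq(0.08, 1, length.out = 2 * len)
    px <- round(cx + t * len * cos(theta))
    py <- round(cy + t * len * sin(theta))
    keep <- px >= 1 & px <= n & py >= 1 & py <= n
    img[cbind(py[keep], px[keep])] <- img[cbind(py[keep], px[keep])] + amp
  }
  img
}

#' Generate one synthetic labeled mammogram
#'
#' Class structure on a smooth textured background: N background only; BM/M
#' bright Gaussian blobs (M brighter and larger); BC/CALC clusters of 1-3 px
#' bright speckles (CALC denser); AD radial bright line segments converging
#' on a focus; ASYM a monotone lateral intensity ramp.
#'
#' @param label Class label.
#' @param size Image side (>= 32); defaults to the spec's `image_size`.
#' @param seed Integer seed for this sample.
#' @param spec A [synthetic_spec()] providing noise and lesion parameters.
#' @return A [labeled_sample()] with `source = "synthetic"` and the seed
#'   attached as attribute `"seed"`.
#' @export
generate_sample <- function(label, size = spec$image_size, seed = spec$seed,
                            spec = synthetic_spec()) {
  if (!label %in% spec$class_set) {
    stop(sprintf("unknown label '%s' (class set: %s)", label,
                 paste(spec$class_set, collapse = ", ")))
  }
  stopifnot(size >= 32)
  L <- spec$lesion_intensity
  r <- spec$lesion_radius_px
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  img <- synth_background(size)
  mid <- function() runif(1, 0.25 * size, 0.75 * size)
  if (label %in% c("BM", "M")) {
    nb <- if (label == "M") sample(1:3, 1) else sample(1:2, 1)
    amp <- if (label == "M") L else 0.6 * L
    rad <- if (label == "M") 1.3 * r else r
    for (b in seq_len(nb)) img <- add_blob(img, mid(), mid(), rad, amp)
  } else if (label %in% c("BC", "CALC")) {
    dense <- label == "CALC"
    k <- if (dense) sample(15:30, 1) else sample(5:10, 1)
    amp <- if (dense) L else 0.8 * L
    img <- add_speckles(img, mid(), mid(), spread = r, k = k, amp = amp)
  } else if (label == "AD") {
    img <- add_radial_lines(img, mid(), mid(), k = sample(6:10, 1),
                            len = 2 * r, amp = 0.6 * L)
  } else if (label == "ASYM") {
    ramp <- matrix(rep(seq(0, 0.6 * L, length.out = size), each = size), size)
    img <- img + ramp
  }
  if (spec$noise_sd > 0) img <- img + rnorm(size^2, 0, spec$noise_sd)
  out <- labeled_sample(pmin(pmax(img, 0), 1), label, spec$class_set,
                        source = "synthetic")
  attr(out, "seed") <- as.integer(seed)
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a full synthetic labeled dataset
#'
#' Per-class counts follow the spec exactly; samples are shuffled
#' deterministically by the spec seed. Each sample draws from its own seed,
#' derived by hashing (global seed, index), so generation is a pure function
#' of the spec.
#'
#' @param spec A [synthetic_spec()].
#' @param split Split tag stored on the dataset.
#' @return A `labeled_dataset` with fields `samples`, `class_set`, `split`.
#' @export
generate_dataset <- function(spec, split = c("train", "val", "test")) {
  split <- match.arg(split)
  labels <- rep(names(spec$class_counts), times = spec$class_counts)
  samples <- lapply(seq_along(labels), function(i) {
    generate_sample(labels[i], size = spec$image_size,
                    seed = derive_seed(spec$seed, i), spec = spec)
  })
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(spec$seed, 0L))
  samples <- samples[sample.int(length(samples))]
  structure(list(samples = samples, class_set = spec$class_set, split = split),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  tab <- table(factor(vapply(x$samples, `[[`, "", "label"),
                      levels = x$class_set))
  cat(sprintf("<labeled_dataset> %d samples (%s split)\n",
              length(x$samples), x$split))
  print(tab)
  invisible(x)
}

dataset_labels <- function(ds) vapply(ds$samples, `[[`, "", "label")

#' Stratified train/validation/test split
#'
#' Partitions a dataset into disjoint, exhaustive splits, stratified per class
#' where counts permit; fractional seats left after flooring go to the splits
#' with the largest remainders (train first on ties).
#'
#' @param ds A `labeled_dataset`.
#' @param fractions Length-3 positive numeric `(train, val, test)` summing
#'   to 1 within 1e-9.
#' @param seed Integer seed controlling the within-class shuffle.
#' @return A list of three `labeled_dataset`s named `train`, `val`, `test`.
#' @export
split_dataset <- function(ds, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(fractions) != 3 || any(fractions <= 0)) {
    stop("fractions must be 3 positive numbers")
  }
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  labs <- dataset_labels(ds)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  assign <- integer(length(labs))
  for (cl in unique(labs)) {
    idx <- sample(which(labs == cl))
    n <- length(idx)
    base <- floor(n * fractions)
    rem <- n * fractions - base
    for (k in seq_len(n - sum(base))) {
      j <- which.max(rem); base[j] <- base[j] + 1; rem[j] <- -1
    }
    assign[idx] <- rep(1:3, times = base)
  }
  mk <- function(k, tag) {
    structure(list(samples = ds$samples[assign == k],
                   class_set = ds$class_set, split = tag),
              class = "labeled_dataset")
  }
  list(train = mk(1, "train"), val = mk(2, "val"), test = mk(3, "test"))
}

#' Write a dataset to disk as PNGs plus a manifest
#'
#' Layout is `<split>/<label>/<index>.png` under `dir`, with a
#' `manifest.csv` of columns path, label, split, source, seed.
#'
#' @param ds A `labeled_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest data frame.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(ds$samples), function(i) {
    s <- ds$samples[[i]]
    sub <- file.path(dir, ds$split, s$label)
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    p <- file.path(sub, sprintf("%05d.png", i))
    save_image(s$image, p)
    sd <- attr(s, "seed")
    data.frame(path = file.path(ds$split, s$label, basename(p)),
               label = s$label, split = ds$split, source = s$source,
               seed = if (is.null(sd)) NA_integer_ else sd)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset previously written by [write_dataset()]
#'
#' @param dir Directory containing `manifest.csv`.
#' @param split Which split to load.
#' @param class_set Class set for the dataset.
#' @return A `labeled_dataset`.
#' @export
read_dataset <- function(dir, split = "train", class_set = mammo_classes()) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  manifest <- manifest[manifest$split == split, , drop = FALSE]
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    labeled_sample(load_image(file.path(dir, manifest$path[i])),
                   manifest$label[i], class_set,
                   source = manifest$source[i])
  })
  structure(list(samples = samples, class_set = class_set, split = split),
            class = "labeled_dataset")
}
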