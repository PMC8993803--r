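# End-to-end orchestration: synthesize (or ingest) -> GAN augment ->
# CLAHE -> seam carve -> wavelet decompose (LL) -> train CNN/wCNN ->
# evaluate. One global seed fans out to per-stage seeds by a stable hash so
# a rerun with the same config reproduces every numeric artifact on CPU.

#' Pipeline configuration
#'
#' Stage order is fixed (synthesis, GAN augmentation, CLAHE, seam carving,
#' wavelet decomposition, training, evaluation); the GAN stage is optional.
#'
#' @param out_dir Output directory for artifacts and the run manifest.
#' @param image_size Side of the synthetic working images.
#' @param class_counts Named per-class sample counts for synthesis.
#' @param seed Global seed; all stage seeds derive from it.
#' @param fractions Train/val/test split fractions.
#' @param clahe A [clahe_params()].
#' @param carve_frac Fraction of each dimension removed by seam carving.
#' @param depth Wavelet decomposition depth; the deepest LL feeds the
#'   network.
#' @param arch `"wcnn"` or `"cnn"`.
#' @param beta Wavelet activation frequency.
#' @param n_blocks,convs_per_block,filters_per_block Network shape for the
#'   working scale.
#' @param pooling Pooling kind for the network blocks (`"avg"` default at
#'   this scale; see [network_spec()]).
#' @param train A [train_config()].
#' @param gan_augment Enable the GAN augmentation stage.
#' @param gan_class Class to synthesize when augmenting.
#' @param gan_n Number of GAN samples to add.
#' @param gan_steps Adversarial steps for GAN training.
#' @param gan_spec A [gan_spec()]; must match `image_size`.
#' @param save_images Write per-stage PNGs (metrics/manifest are always
#'   written).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            image_size = 64L,
                            class_counts = c(N = 50, BC = 50, BM = 50,
                                             CALC = 50, M = 50),
                            seed = 1L,
                            fractions = c(0.7, 0.15, 0.15),
                            clahe = clahe_params(),
                            carve_frac = 0.05,
                            depth = 2L,
                            arch = c("wcnn", "cnn"),
                            beta = 0.5,
                            n_blocks = 2L,
                            convs_per_block = 1L,
                            filters_per_block = c(16L, 32L),
                            pooling = "avg",
                            train = train_config(learning_rate = 3e-4,
                                                 batch_size = 8L,
                                                 epochs = 3L),
                            gan_augment = FALSE,
                            gan_class = "CALC",
                            gan_n = 16L,
                            gan_steps = 50L,
                            gan_spec = NULL,
                            save_images = TRUE) {
  arch <- match.arg(arch)
  structure(list(out_dir = out_dir, image_size = as.integer(image_size),
                 class_counts = class_counts, seed = as.integer(seed),
                 fractions = fractions, clahe = clahe,
                 carve_frac = carve_frac, depth = as.integer(depth),
                 arch = arch, beta = beta, n_blocks = as.integer(n_blocks),
                 convs_per_block = as.integer(convs_per_block),
                 filters_per_block = as.integer(filters_per_block),
                 pooling = pooling, train = train, gan_augment = gan_augment,
                 gan_class = gan_class, gan_n = as.integer(gan_n),
                 gan_steps = as.integer(gan_steps), gan_spec = gan_spec,
                 save_images = save_images),
            class = "pipeline_config")
}

pipeline_stage_names <- function() {
  c("synth", "gan", "clahe", "carve", "wavelet", "train", "evaluate")
}

apply_to_dataset <- function(ds, f) {
  ds$samples <- lapply(ds$samples, function(s) { s$image <- f(s$image); s })
  ds
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order and writes a JSON run manifest, the
#' per-epoch training history CSV and the test-set metrics CSV under
#' `cfg$out_dir`. A rerun with an identical config reproduces the numeric
#' artifacts bit for bit.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, the manifest list (stages, config echo, metrics).
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  t0 <- Sys.time()

  # synth
  spec <- synthetic_spec(image_size = cfg$image_size,
                         class_counts = cfg$class_counts,
                         seed = derive_seed(cfg$seed, 1L))
  ds <- generate_dataset(spec)
  splits <- split_dataset(ds, cfg$fractions, seed = derive_seed(cfg$seed, 2L))
  splits$val$split <- "val"; splits$test$split <- "test"
  stages$synth <- list(status = "done", n = length(ds$samples))

  # gan (optional augmentation of the training split)
  if (isTRUE(cfg$gan_augment)) {
    gspec <- cfg$gan_spec
    if (is.null(gspec)) {
      gspec <- gan_spec(output_size = cfg$image_size,
                        gen_filters = c(64L, 32L, 16L, 8L),
                        disc_filters = c(8L, 16L, 32L, 64L))
    }
    cls_ds <- splits$train
    cls_ds$samples <- cls_ds$samples[dataset_labels(cls_ds) == cfg$gan_class]
    gt <- train_gan(cls_ds,
                    gan_train_config(batch_size = min(32L, length(cls_ds$samples)),
                                     steps = cfg$gan_steps,
                                     seed = derive_seed(cfg$seed, 3L)),
                    gspec)
    new <- synthesize(gt$generator, cfg$gan_n, cfg$gan_class,
                      seed = derive_seed(cfg$seed, 4L),
                      class_set = splits$train$class_set)
    splits$train <- augment_dataset(splits$train, new)
    stages$gan <- list(status = "done", added = cfg$gan_n)
  } else {
    stages$gan <- list(status = "skipped")
  }

  # clahe -> carve -> wavelet, applied identically to every split
  for (nm in names(splits)) {
    splits[[nm]] <- apply_to_dataset(splits[[nm]],
                                     function(im) apply_clahe(im, cfg$clahe))
  }
  stages$clahe <- list(status = "done")
  nv <- floor(cfg$image_size * cfg$carve_frac)
  for (nm in names(splits)) {
    splits[[nm]] <- apply_to_dataset(splits[[nm]],
                                     function(im) carve(im, nv, nv))
  }
  stages$carve <- list(status = "done", seams_removed = nv)
  for (nm in names(splits)) {
    splits[[nm]] <- apply_to_dataset(splits[[nm]],
                                     function(im) wavelet_features(im, cfg$depth))
  }
  ll_side <- dim(splits$train$samples[[1]]$image)[1]
  stages$wavelet <- list(status = "done", depth = cfg$depth,
                         ll_side = ll_side)
  if (isTRUE(cfg$save_images)) {
    for (nm in names(splits)) write_dataset(splits[[nm]],
                                            file.path(cfg$out_dir, "ll"))
  }

  # train
  nspec <- network_spec(input_size = ll_side, n_blocks = cfg$n_blocks,
                        convs_per_block = cfg$convs_per_block,
                        filters_per_block = cfg$filters_per_block,
                        activation = if (cfg$arch == "wcnn") "wavelet" else "relu",
                        activation_params = activation_params(cfg$beta),
                        n_classes = length(splits$train$class_set),
                        pooling = cfg$pooling)
  tcfg <- cfg$train
  tcfg$seed <- derive_seed(cfg$seed, 5L)
  set.seed(derive_seed(cfg$seed, 6L))      # weight initialization
  model <- if (cfg$arch == "wcnn") build_wcnn(nspec) else build_cnn(nspec)
  history <- train_model(model, splits$train, splits$val, tcfg)
  write.csv(history, file.path(cfg$out_dir, "history.csv"), row.names = FALSE)
  stages$train <- list(status = "done", epochs = tcfg$epochs,
                       final_val_acc = history$val_acc[nrow(history)])

  # evaluate
  pred <- predict_classes(model, splits$test)
  report <- metrics_report(dataset_labels(splits$test), pred$labels,
                           splits$test$class_set)
  write_metrics(report, file.path(cfg$out_dir, "metrics.csv"))
  stages$evaluate <- list(status = "done", accuracy = report$accuracy)

  manifest <- list(
    package = "mammowave",
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), c("clahe", "train", "gan_spec"))],
    clahe = unclass(cfg$clahe),
    train_config = unclass(cfg$train),
    stages = stages,
    class_set = splits$train$class_set,
    metrics = report[c("accuracy", "specificity", "precision", "f1",
                       "recall", "sensitivity")],
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Compare two pipeline runs
#'
#' Side-by-side table of the metric suites recorded in two run manifests.
#'
#' @param run_a,run_b Output directories of completed [run_pipeline()] runs.
#' @return A data frame with one row per run and one column per metric.
#' @export
compare_runs <- function(run_a, run_b) {
  read_run <- function(dir) {
    p <- file.path(dir, "manifest.json")
    if (!file.exists(p)) stop(sprintf("no manifest in '%s'", dir))
    jsonlite::read_json(p, simplifyVector = TRUE)
  }
  a <- read_run(run_a); b <- read_run(run_b)
  if (is.null(a$metrics) || is.null(b$metrics)) {
    stop("both runs must contain a metrics report")
  }
  if (!identical(a$class_set, b$class_set)) {
    stop("runs have incompatible class sets")
  }
  keys <- c("accuracy", "specificity", "precision", "f1", "recall",
            "sensitivity")
  out <- rbind(data.frame(run = run_a, arch = a$config$arch,
                          t(unlist(a$metrics[keys]))),
               data.frame(run = run_b, arch = b$config$arch,
                          t(unlist(b$metrics[keys]))))
  rownames(out) <- NULL
  out
}
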