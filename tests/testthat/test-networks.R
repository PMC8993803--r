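conv_layers <- function(model) {
  Filter(function(ly) ly$type == "conv", model$layers)
}

test_that("default architecture: 6 blocks x 3 convs, 3x3, dropout, L2, softmax", {
  spec <- network_spec()
  expect_equal(spec$input_size, 299L)
  m <- build_cnn(network_spec(activation = "relu"))
  convs <- conv_layers(m)
  expect_length(convs, 18)                        # 6 blocks x 3 layers
  for (ly in convs) {
    expect_equal(dim(ly$W)[1:2], c(3L, 3L))
    expect_equal(ly$l2, 2e-4)
  }
  # filter schedule 32..512 with the cap repeated
  expect_equal(vapply(convs, function(ly) dim(ly$W)[4], 0L)[seq(1, 18, 3)],
               c(32L, 64L, 128L, 256L, 512L, 512L))
  types <- vapply(m$layers, `[[`, "", "type")
  expect_equal(sum(types == "pool"), 6)
  # dropout 0.5 sits right after flatten, before the dense softmax head
  fi <- which(types == "flatten")
  expect_equal(types[fi + 1], "dropout")
  expect_equal(m$layers[[fi + 1]]$rate, 0.5)
  expect_equal(types[fi + 2], "dense")
  expect_equal(nrow(m$layers[[fi + 2]]$W), 5)     # softmax over 5 classes
})

test_that("CNN and wCNN are structurally identical, differing in activation", {
  sp_r <- network_spec(input_size = 32, n_blocks = 2, convs_per_block = 2,
                       filters_per_block = c(4L, 8L), activation = "relu",
                       n_classes = 3)
  sp_w <- network_spec(input_size = 32, n_blocks = 2, convs_per_block = 2,
                       filters_per_block = c(4L, 8L), activation = "wavelet",
                       n_classes = 3)
  set.seed(20); cnn <- build_cnn(sp_r)
  set.seed(20); wcnn <- build_wcnn(sp_w)
  expect_equal(nn_count_params(cnn), nn_count_params(wcnn))
  expect_equal(vapply(cnn$layers, `[[`, "", "type"),
               vapply(wcnn$layers, `[[`, "", "type"))
  acts_c <- Filter(function(l) l$type == "act", cnn$layers)
  acts_w <- Filter(function(l) l$type == "act", wcnn$layers)
  expect_true(all(vapply(acts_c, function(l) l$fn$name, "") == "relu"))
  expect_true(all(vapply(acts_w, function(l) l$fn$name, "") == "wavelet"))
  # same seed, same weights, different outputs on a nonzero input
  X <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  oc <- mammowave:::nn_forward(cnn, X)$out
  ow <- mammowave:::nn_forward(wcnn, X)$out
  expect_false(isTRUE(all.equal(oc, ow)))
  # parameter-count equality also holds at the default full scale
  set.seed(21); big_c <- build_cnn(network_spec(activation = "relu"))
  set.seed(21); big_w <- build_wcnn(network_spec(activation = "wavelet"))
  expect_equal(nn_count_params(big_c), nn_count_params(big_w))
})

test_that("softmax rows normalize and builds are seed-deterministic", {
  sp <- compact_wcnn_spec(input_size = 32, n_classes = 4)
  set.seed(30); m1 <- build_wcnn(sp)
  set.seed(30); m2 <- build_wcnn(sp)
  X <- array(runif(32 * 32 * 3), c(32, 32, 1, 3))
  p1 <- predict_classes(m1, lapply(1:3, function(i) X[, , 1, i]),
                        class_set = letters[1:4])
  p2 <- predict_classes(m2, lapply(1:3, function(i) X[, , 1, i]),
                        class_set = letters[1:4])
  expect_equal(rowSums(p1$probs), rep(1, 3), tolerance = 1e-6)
  expect_identical(p1$probs, p2$probs)
  expect_true(all(p1$labels %in% letters[1:4]))
})

test_that("spatial collapse is caught at build time", {
  expect_error(network_spec(input_size = 8, n_blocks = 6,
                            filters_per_block = rep(4L, 6)),
               "collapses")
})

test_that("training bookkeeping: history length, finite values, null step", {
  data <- two_class_data(seed = 77, n_train_per_class = 8,
                         n_val_per_class = 4, size = 32)
  sp <- compact_wcnn_spec(input_size = 32)
  set.seed(40)
  m <- build_wcnn(sp)
  h <- train_model(m, data$train, data$val,
                   train_config(learning_rate = 1e-3, batch_size = 4,
                                epochs = 3, seed = 1))
  expect_s3_class(h, "data.frame")
  expect_equal(nrow(h), 3)
  expect_true(all(is.finite(unlist(h))))
  # learning_rate = 0: no parameter ever moves
  set.seed(41)
  m0 <- build_wcnn(sp)
  before <- predict_classes(m0, lapply(data$val$samples, `[[`, "image"),
                            class_set = c("N", "M"))$probs
  train_model(m0, data$train, data$val,
              train_config(learning_rate = 0, batch_size = 4, epochs = 1,
                           seed = 2))
  after <- predict_classes(m0, lapply(data$val$samples, `[[`, "image"),
                           class_set = c("N", "M"))$probs
  expect_identical(before, after)
  empty <- data$train; empty$samples <- list()
  expect_error(train_model(m, empty, data$val,
                           train_config(epochs = 1)), "empty")
})

test_that("one optimization step changes the loss (gradient flows at init)", {
  data <- two_class_data(seed = 55, n_train_per_class = 4,
                         n_val_per_class = 4, size = 32)
  sp <- compact_wcnn_spec(input_size = 32)
  set.seed(50)
  m <- build_wcnn(sp)
  eval0 <- mammowave:::model_eval(m, mammowave:::dataset_batch(data$val)$X,
                                  mammowave:::dataset_batch(data$val)$Y)
  train_model(m, data$train, data$val,
              train_config(learning_rate = 1e-3, batch_size = 8, epochs = 1,
                           seed = 3))
  eval1 <- mammowave:::model_eval(m, mammowave:::dataset_batch(data$val)$X,
                                  mammowave:::dataset_batch(data$val)$Y)
  expect_false(isTRUE(all.equal(eval0$loss, eval1$loss)))
})

test_that("seeded training runs are bit-reproducible", {
  data <- two_class_data(seed = 66, n_train_per_class = 6,
                         n_val_per_class = 4, size = 32)
  sp <- compact_wcnn_spec(input_size = 32)
  run <- function() {
    set.seed(60)
    m <- build_wcnn(sp)
    train_model(m, data$train, data$val,
                train_config(learning_rate = 1e-3, batch_size = 4,
                             epochs = 2, seed = 4))
  }
  expect_identical(run(), run())
})
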