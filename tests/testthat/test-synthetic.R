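test_that("generation is a pure function of (label, size, seed, spec)", {
  spec <- synthetic_spec(image_size = 48, seed = 3)
  a <- generate_sample("CALC", size = 48, seed = 99, spec = spec)
  b <- generate_sample("CALC", size = 48, seed = 99, spec = spec)
  expect_identical(a$image, b$image)
  c <- generate_sample("CALC", size = 48, seed = 100, spec = spec)
  expect_false(identical(a$image, c$image))
  expect_error(generate_sample("XYZ", size = 48, seed = 1, spec = spec),
               "unknown label")
})

test_that("normals are pure background and masses rise above them", {
  spec <- synthetic_spec(image_size = 64, seed = 5, noise_sd = 0,
                         lesion_intensity = 0.5)
  for (s in c(11, 22, 33)) {
    n_img <- generate_sample("N", size = 64, seed = s, spec = spec)$image
    m_img <- generate_sample("M", size = 64, seed = s, spec = spec)$image
    # background stays in the low-contrast band; a mass adds its peak on top
    expect_lt(max(n_img), 0.5)
    expect_gte(max(m_img) - max(n_img), spec$lesion_intensity / 2)
  }
})

test_that("class structure matches its description", {
  spec <- synthetic_spec(image_size = 64, seed = 1, noise_sd = 0)
  # ASYM: monotone lateral ramp -> right side brighter than left
  a <- generate_sample("ASYM", size = 64, seed = 2,
                       spec = synthetic_spec(image_size = 64,
                                             class_counts = c(ASYM = 1),
                                             seed = 1, noise_sd = 0))$image
  expect_gt(mean(a[, 49:64]) - mean(a[, 1:16]), 0.1)
  # CALC: sparse bright speckles -> high-intensity pixel count small but > 0
  cc <- generate_sample("CALC", size = 64, seed = 2, spec = spec)$image
  nn <- generate_sample("N", size = 64, seed = 2, spec = spec)$image
  expect_gt(sum(cc > max(nn) + 0.1), 0)
  expect_lt(sum(cc > max(nn) + 0.1), 0.05 * length(cc))
})

test_that("datasets honor class counts and are deterministically shuffled", {
  spec <- synthetic_spec(image_size = 32, class_counts = c(N = 3, M = 2),
                         seed = 9)
  ds <- generate_dataset(spec)
  expect_length(ds$samples, 5)
  tab <- table(vapply(ds$samples, `[[`, "", "label"))
  expect_equal(as.integer(tab[c("N", "M")]), c(3, 2))
  ds2 <- generate_dataset(spec)
  expect_identical(lapply(ds$samples, `[[`, "image"),
                   lapply(ds2$samples, `[[`, "image"))
  spec3 <- synthetic_spec(image_size = 32, class_counts = c(N = 3, M = 2),
                          seed = 10)
  ds3 <- generate_dataset(spec3)
  expect_false(identical(ds$samples[[1]]$image, ds3$samples[[1]]$image))
  expect_error(synthetic_spec(class_counts = c(N = -1)), "non-negative")
})

test_that("split_dataset partitions exhaustively, disjointly, stratified", {
  spec <- synthetic_spec(image_size = 32,
                         class_counts = c(N = 10, M = 10), seed = 2)
  ds <- generate_dataset(spec)
  sp <- split_dataset(ds, c(0.8, 0.1, 0.1), seed = 4)
  expect_equal(vapply(sp, function(d) length(d$samples), 0L),
               c(train = 16L, val = 2L, test = 2L))
  # per-class stratification: 10 * (0.8, 0.1, 0.1) exactly
  for (cl in c("N", "M")) {
    cnt <- vapply(sp, function(d) sum(vapply(d$samples, `[[`, "", "label") == cl), 0L)
    expect_equal(unname(cnt), c(8L, 1L, 1L))
  }
  # union of splits = original multiset of images
  key <- function(s) paste(round(s$image[1:6], 10), collapse = ",")
  all_keys <- sort(unname(unlist(lapply(sp, function(d) vapply(d$samples, key, "")))))
  expect_equal(all_keys, sort(vapply(ds$samples, key, "")))
  sp2 <- split_dataset(ds, c(0.8, 0.1, 0.1), seed = 4)
  expect_identical(lapply(sp$train$samples, `[[`, "image"),
                   lapply(sp2$train$samples, `[[`, "image"))
  expect_error(split_dataset(ds, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("a max-intensity threshold separates N from M on 200 samples", {
  # separability guarantee for the learning task: with low noise and the
  # default lesion contrast the classes are linearly separable on one feature
  spec <- synthetic_spec(image_size = 64, class_counts = c(N = 100, M = 100),
                         seed = 31, noise_sd = 0.02, lesion_intensity = 0.5)
  ds <- generate_dataset(spec)
  labs <- vapply(ds$samples, `[[`, "", "label")
  mx <- vapply(ds$samples, function(s) max(s$image), 0)
  thr <- 0.55
  acc <- mean((mx > thr) == (labs == "M"))
  expect_gte(acc, 0.95)
})

test_that("write_dataset/read_dataset round-trip the manifest layout", {
  d <- withr::local_tempdir()
  spec <- synthetic_spec(image_size = 32, class_counts = c(N = 2, M = 2),
                         seed = 6)
  ds <- generate_dataset(spec)
  man <- write_dataset(ds, d)
  expect_true(file.exists(file.path(d, "manifest.csv")))
  expect_setequal(colnames(man), c("path", "label", "split", "source", "seed"))
  back <- read_dataset(d, "train")
  expect_length(back$samples, 4)
  expect_setequal(vapply(back$samples, `[[`, "", "label"),
                  vapply(ds$samples, `[[`, "", "label"))
})
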