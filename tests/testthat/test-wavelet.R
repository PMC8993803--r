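test_that("one level yields four subbands matching the 2x2 oracle", {
  b <- dwt2_haar(matrix(c(0.2, 0.6, 0.4, 0.8), 2, 2))  # [[a,c],[b,d]] col-major
  expect_named(b[1:4], c("LL", "HL", "LH", "HH"), ignore.order = TRUE)
  o <- oracle_haar_2x2(a = 0.2, b = 0.4, c = 0.6, d = 0.8)  # [[a,b],[c,d]] row-major
  expect_equal(as.numeric(b$LL), o$LL)
  expect_equal(as.numeric(b$LH), o$LH)
  expect_equal(as.numeric(b$HL), o$HL)
  expect_equal(as.numeric(b$HH), o$HH)
  # constant image: LL = 2c, all details zero
  bc <- dwt2_haar(matrix(0.3, 6, 6))
  expect_equal(bc$LL, matrix(0.6, 3, 3))
  expect_equal(bc$LH, matrix(0, 3, 3))
  expect_equal(bc$HL, matrix(0, 3, 3))
  expect_equal(bc$HH, matrix(0, 3, 3))
  expect_error(dwt2_haar(matrix(1, 1, 4)), "2x2")
})

test_that("subband orientation follows the x/y filter convention", {
  # vertical stripes (variation along x only) -> detail lives in LH
  stripes <- matrix(rep(c(0, 1), 4), 4, 8, byrow = TRUE)
  b <- dwt2_haar(stripes)
  expect_gt(sum(b$LH^2), 0)
  expect_equal(sum(b$HL^2) + sum(b$HH^2), 0, tolerance = 1e-12)
  # horizontal stripes -> HL
  b2 <- dwt2_haar(t(stripes))
  expect_equal(sum(b2$LH^2) + sum(b2$HH^2), 0, tolerance = 1e-12)
  expect_gt(sum(b2$HL^2), 0)
})

test_that("perfect reconstruction and Parseval hold on seeded images", {
  for (s in 1:10) {
    n <- sample(c(8, 12, 16, 31, 33, 64), 1)
    m <- sample(c(8, 12, 16, 31, 33, 64), 1)
    x <- rand_img(n, m, seed = s)
    b <- dwt2_haar(x)
    expect_lt(max(abs(idwt2_haar(b) - x)), 1e-8)
    if (n %% 2 == 0 && m %% 2 == 0) {
      e_in <- sum(x^2)
      e_out <- sum(b$LL^2) + sum(b$LH^2) + sum(b$HL^2) + sum(b$HH^2)
      expect_lt(abs(e_out - e_in) / e_in, 1e-8)
    }
  }
  # explicit odd case from the synthesis contract
  x57 <- rand_img(5, 7, seed = 99)
  expect_lt(max(abs(idwt2_haar(dwt2_haar(x57)) - x57)), 1e-8)
  z <- dwt2_haar(matrix(0, 4, 4))
  expect_equal(idwt2_haar(z), matrix(0, 4, 4))
})

test_that("max_level is the integer halving depth of the smaller side", {
  expect_identical(max_level(c(299, 299)), 8L)
  # independent oracle: count halvings until below 2
  halvings <- function(k) { n <- 0L; while (k >= 2) { k <- k / 2; n <- n + 1L }; n }
  expect_identical(max_level(c(299, 299)), halvings(299))
  expect_identical(max_level(c(2, 2)), 1L)
  expect_identical(max_level(c(8, 4)), 2L)
  expect_error(max_level(c(1, 8)), "at least 2")
})

test_that("the Mallat pyramid recurses on LL with halving shapes", {
  x <- rand_img(16, 16, seed = 3)
  p1 <- wavedec2(x, depth = 1)
  expect_equal(p1$levels[[1]]$LL, dwt2_haar(x)$LL)
  p3 <- wavedec2(x, depth = 3)
  expect_equal(dim(p3$levels[[3]]$LL), c(2, 2))
  expect_equal(p3$levels[[2]], dwt2_haar(p3$levels[[1]]$LL))
  # constant image at depth 2: LL = 4c, details zero at both levels
  pc <- wavedec2(matrix(0.2, 8, 8), depth = 2)
  expect_equal(pc$levels[[2]]$LL, matrix(0.8, 2, 2))
  for (k in 1:2) for (bnd in c("LH", "HL", "HH")) {
    expect_equal(max(abs(pc$levels[[k]][[bnd]])), 0)
  }
  expect_error(wavedec2(x, depth = 5), "depth")
})

test_that("pyramid energy is conserved across levels (even dims)", {
  x <- rand_img(32, 32, seed = 21)
  p <- wavedec2(x, depth = 3)
  e <- sum(p$levels[[3]]$LL^2)
  for (k in 1:3) for (bnd in c("LH", "HL", "HH")) {
    e <- e + sum(p$levels[[k]][[bnd]]^2)
  }
  expect_lt(abs(e - sum(x^2)) / sum(x^2), 1e-8)
})

test_that("extract_ll returns the deepest normalized approximation", {
  x <- rand_img(20, 20, seed = 6)
  p <- wavedec2(x, depth = 2)
  ll <- extract_ll(p)
  expect_equal(dim(ll), c(5, 5))
  expect_equal(ll, normalize_image(p$levels[[2]]$LL))
  expect_equal(extract_ll(wavedec2(x, 1)), normalize_image(dwt2_haar(x)$LL))
  # constant image -> all-zero normalized LL by convention
  expect_equal(extract_ll(wavedec2(matrix(0.4, 8, 8), 1)), matrix(0, 4, 4))
  expect_equal(dim(wavelet_features(x, 2)), c(5, 5))
})

test_that("packet mode decomposes every subband", {
  x <- rand_img(8, 8, seed = 10)
  p <- wavedec2(x, depth = 2, packet = TRUE)
  expect_length(p$levels[[2]], 4)              # 4 children at level 2
  expect_s3_class(p$levels[[1]], "subband_set")
  # first child of level 2 is the decomposition of level 1's LL
  expect_equal(p$levels[[2]][[1]], dwt2_haar(p$levels[[1]]$LL))
  expect_equal(dim(extract_ll(p)), c(2, 2))
})
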