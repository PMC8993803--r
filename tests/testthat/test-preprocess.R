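test_that("CLAHE keeps shape and range and spreads low-contrast histograms", {
  const <- matrix(0.5, 32, 32)
  expect_equal(apply_clahe(const), const)       # nothing to equalize
  set.seed(12)
  low <- matrix(runif(64 * 64, 0.4, 0.6), 64, 64)
  out <- apply_clahe(low)
  expect_equal(dim(out), dim(low))
  expect_true(min(out) >= 0 && max(out) <= 1)
  expect_gte(sd(out), sd(low))
  expect_error(apply_clahe(matrix(runif(16), 4, 4),
                           clahe_params(tile_grid = c(8, 8))),
               "tile grid")
})

test_that("energy map matches the per-pixel finite-difference oracle", {
  expect_equal(compute_energy(matrix(0.3, 5, 5)), matrix(0, 5, 5))
  expect_equal(total_energy(matrix(0.3, 5, 5)), 0)
  x22 <- matrix(c(0, 0, 1, 1), 2, 2)       # [[0,1],[0,1]]
  expect_equal(compute_energy(x22), oracle_energy(x22))
  for (s in 1:5) {
    img <- rand_img(6, 7, seed = s)
    expect_equal(compute_energy(img), oracle_energy(img))
  }
  expect_error(compute_energy(matrix(1, 1, 5)), "2x2")
})

test_that("a single bright pixel has energy confined to its neighborhood", {
  img <- matrix(0, 7, 7)
  img[4, 4] <- 1
  E <- compute_energy(img)
  nz <- which(E > 0, arr.ind = TRUE)
  expect_true(all(abs(nz[, 1] - 4) + abs(nz[, 2] - 4) <= 2))
  expect_true(all(E[cbind(c(4, 3, 5), c(3, 4, 4))] > 0))
})

test_that("DP seam equals the exhaustive minimum and honors tie-breaks", {
  # stated tie-break: all-zero energy -> first column/row throughout
  z <- matrix(0, 4, 4)
  expect_equal(find_min_seam(z, "vertical")$indices, rep(1L, 4))
  expect_equal(find_min_seam(z, "horizontal")$indices, rep(1L, 4))
  mid <- matrix(1, 3, 3); mid[, 2] <- 0
  expect_equal(find_min_seam(mid, "vertical")$indices, rep(2L, 3))
  # optimality against enumeration on random maps
  for (s in 1:25) {
    E <- matrix(runif(36), 6, 6)
    sv <- find_min_seam(E, "vertical")
    expect_true(all(abs(diff(sv$indices)) <= 1))
    expect_equal(sum(E[cbind(1:6, sv$indices)]), oracle_min_seam_energy(E))
    sh <- find_min_seam(E, "horizontal")
    expect_equal(sum(E[cbind(sh$indices, 1:6)]), oracle_min_seam_energy(t(E)))
  }
})

test_that("remove_seam deletes exactly the seam pixels, preserving order", {
  img <- matrix(1:9 / 10, 3, 3, byrow = TRUE)
  s0 <- structure(list(kind = "vertical", indices = rep(1L, 3)),
                  class = "seam")
  expect_equal(remove_seam(img, s0), img[, 2:3])
  set.seed(3)
  x <- matrix(runif(30), 5, 6)
  sv <- find_min_seam(compute_energy(x), "vertical")
  y <- remove_seam(x, sv)
  expect_equal(dim(y), c(5, 5))                     # height unchanged
  for (i in 1:5) {
    expect_equal(y[i, ], x[i, -sv$indices[i]])      # row order preserved
  }
  bad <- structure(list(kind = "vertical", indices = rep(1L, 4)),
                   class = "seam")
  expect_error(remove_seam(x, bad), "match")
})

test_that("carve reduces shape exactly, deterministically, keeping blobs", {
  x <- rand_img(10, 10, seed = 5)
  expect_equal(carve(x, 0, 0), x)
  expect_equal(carve(matrix(0, 5, 5), 2, 0), matrix(0, 5, 3))
  expect_equal(dim(carve(x, 3, 2)), c(8, 7))
  expect_identical(carve(x, 3, 2), carve(x, 3, 2))
  expect_error(carve(x, 9, 0), "exceeds")
  # a bright blob is high-energy: its pixels survive carving
  img <- matrix(0.2, 20, 20)
  img[9:12, 9:12] <- 0.9
  out <- carve(img, 6, 0)
  expect_equal(sum(out == 0.9), 16)
})

test_that("total energy never grows across seam removals of a smooth image", {
  img <- rand_img(12, 12, seed = 8)
  e0 <- total_energy(img)
  out <- carve(img, 4, 0)
  # removing min-energy seams may create new edges at the junction, but at
  # this smoothness the carved image's total energy stays bounded
  expect_lt(total_energy(out), e0)
  expect_equal(dim(out), c(12, 8))
})
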