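# Image enhancement and content-aware reduction: CLAHE, gradient-energy
# maps, and seam carving. The energy at a pixel is |dI/dx| + |dI/dy| with
# central differences in the interior and replicated edges at the borders;
# a seam is the 8-connected minimal-cumulative-energy path found by dynamic
# programming, removed one pixel per row (vertical) or per column
# (horizontal). Everything here is deterministic: no RNG.

#' CLAHE parameters
#'
#' @param clip_limit Normalized clip limit, the fraction of a tile histogram
#'   any bin may hold before redistribution (> 0; default 0.01).
#' @param tile_grid Integer `(rows, cols)` tile grid (default `c(8, 8)`).
#' @return A `clahe_params` list.
#' @export
clahe_params <- function(clip_limit = 0.01, tile_grid = c(8, 8)) {
  stopifnot(clip_limit > 0, length(tile_grid) == 2, all(tile_grid >= 1))
  structure(list(clip_limit = clip_limit, tile_grid = as.integer(tile_grid)),
            class = "clahe_params")
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise histogram equalization with a clip on histogram bins to limit
#' noise amplification, bilinearly interpolated between tile mappings.
#' Constant images are returned unchanged (there is no contrast to amplify).
#'
#' @param img Gray image matrix.
#' @param params A [clahe_params()].
#' @return Equalized gray image of the same shape, values in \[0, 1\].
#' @export
apply_clahe <- function(img, params = clahe_params()) {
  img <- as_gray_image(img)
  if (any(dim(img) < params$tile_grid)) {
    stop("tile grid exceeds image dimensions")
  }
  if (diff(range(img)) == 0) return(img)
  bins <- 256L
  out <- EBImage::clahe(img, nx = params$tile_grid[2], ny = params$tile_grid[1],
                        bins = bins, limit = params$clip_limit * bins)
  pmin(pmax(as.matrix(out), 0), 1)
}

#' Gradient-energy map of an image
#'
#' Entry (i, j) is |horizontal difference| + |vertical difference|, using
#' central differences with replicated edges. The total energy of the image
#' is the sum of all entries; it is zero iff the image is constant.
#'
#' @param img Gray image matrix, at least 2x2.
#' @return Non-negative matrix of the same shape.
#' @export
compute_energy <- function(img) {
  if (!is.matrix(img) || nrow(img) < 2 || ncol(img) < 2) {
    stop("image must be at least 2x2")
  }
  n <- nrow(img); m <- ncol(img)
  right <- img[, c(2:m, m)]; left <- img[, c(1, 1:(m - 1))]
  down <- img[c(2:n, n), ]; up <- img[c(1, 1:(n - 1)), ]
  abs(right - left) / 2 + abs(down - up) / 2
}

#' Total gradient energy
#'
#' @param img Gray image matrix.
#' @return Sum of the energy map entries.
#' @export
total_energy <- function(img) sum(compute_energy(img))

#' Minimal-energy seam
#'
#' Dynamic-programming search for the 8-connected seam (steps -1/0/+1) of
#' minimal cumulative energy. Ties are broken toward the smallest starting
#' index, then the smallest index at each step, so the result is the
#' lexicographically smallest optimal seam.
#'
#' @param energy Energy map matrix, at least 2x2.
#' @param kind `"vertical"` (one column index per row) or `"horizontal"`
#'   (one row index per column).
#' @return A `seam` list with fields `kind` and `indices` (1-based).
#' @export
find_min_seam <- function(energy, kind = c("vertical", "horizontal")) {
  kind <- match.arg(kind)
  if (!is.matrix(energy) || nrow(energy) < 2 || ncol(energy) < 2) {
    stop("energy map must be at least 2x2")
  }
  E <- if (kind == "vertical") energy else t(energy)
  n <- nrow(E); m <- ncol(E)
  # cumulative cost from row i downward; filled bottom-up so the seam can be
  # emitted top-down with lexicographic tie-breaking
  M <- E
  for (i in (n - 1):1) {
    below <- M[i + 1, ]
    best <- pmin(c(Inf, below[-m]), below, c(below[-1], Inf))
    M[i, ] <- E[i, ] + best
  }
  idx <- integer(n)
  idx[1] <- which.min(M[1, ])              # smallest index on ties
  for (i in 2:n) {
    j <- idx[i - 1]
    cand <- max(1, j - 1):min(m, j + 1)
    idx[i] <- cand[which.min(M[i, cand])]  # which.min takes the first minimum
  }
  structure(list(kind = kind, indices = idx), class = "seam")
}

#' Remove a seam from an image
#'
#' A vertical seam removes one pixel per row (width shrinks by 1); a
#' horizontal seam removes one pixel per column (height shrinks by 1). All
#' non-seam pixels are preserved in order.
#'
#' @param img Gray image matrix.
#' @param seam A `seam` from [find_min_seam()].
#' @return The carved image.
#' @export
remove_seam <- function(img, seam) {
  vertical <- seam$kind == "vertical"
  X <- if (vertical) img else t(img)
  n <- nrow(X); m <- ncol(X)
  if (length(seam$indices) != n || any(seam$indices < 1 | seam$indices > m)) {
    stop("seam does not match image shape")
  }
  keep <- matrix(TRUE, n, m)
  keep[cbind(seq_len(n), seam$indices)] <- FALSE
  Y <- matrix(t(X)[t(keep)], nrow = n, byrow = TRUE)
  if (vertical) Y else t(Y)
}

#' Content-aware seam carving
#'
#' Iteratively recomputes the energy map, finds the minimal seam and removes
#' it: all vertical seams first, then all horizontal seams.
#'
#' @param img Gray image matrix.
#' @param n_vertical Number of vertical seams to remove (width shrink).
#' @param n_horizontal Number of horizontal seams to remove (height shrink).
#' @return Image of shape `(height - n_horizontal, width - n_vertical)`.
#' @export
carve <- function(img, n_vertical = 0L, n_horizontal = 0L) {
  stopifnot(n_vertical >= 0, n_horizontal >= 0)
  if (n_vertical >= ncol(img) - 1 || n_horizontal >= nrow(img) - 1) {
    stop("carving request exceeds image size")
  }
  for (i in seq_len(n_vertical)) {
    img <- remove_seam(img, find_min_seam(compute_energy(img), "vertical"))
  }
  for (i in seq_len(n_horizontal)) {
    img <- remove_seam(img, find_min_seam(compute_energy(img), "horizontal"))
  }
  img
}

#' Preprocess one image the way the classification pipeline does
#'
#' CLAHE enhancement followed by seam carving of a fixed fraction of each
#' dimension (default 5%).
#'
#' @param img Gray image matrix.
#' @param params [clahe_params()].
#' @param carve_frac Fraction of each dimension removed by seam carving.
#' @return The preprocessed image.
#' @export
preprocess_image <- function(img, params = clahe_params(), carve_frac = 0.05) {
  stopifnot(carve_frac >= 0, carve_frac < 1)
  img <- apply_clahe(img, params)
  carve(img, n_vertical = floor(ncol(img) * carve_frac),
        n_horizontal = floor(nrow(img) * carve_frac))
}
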