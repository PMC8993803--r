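# Discrete 2D Haar wavelet analysis/synthesis. Separable orthonormal
# filter bank: scaling response (1, 1)/sqrt(2), wavelet response
# (1, -1)/sqrt(2). Subband naming follows the horizontal/vertical/diagonal
# detail convention with x = column index, y = row index:
#   LL = scaling in x and y (approximation, low pass)
#   LH = wavelet in x, scaling in y (horizontal detail)
#   HL = scaling in x, wavelet in y (vertical detail)
#   HH = wavelet in both (diagonal detail)
# Orthonormality gives perfect reconstruction and Parseval energy
# conservation; a constant image c maps to LL = 2c with all details zero.

# pair-sum / pair-difference along columns (x direction), downsampled by 2
haar_split_cols <- function(X) {
  m <- ncol(X)
  odd <- seq(1, m, by = 2); even <- seq(2, m, by = 2)
  list(lo = (X[, odd, drop = FALSE] + X[, even, drop = FALSE]) / sqrt(2),
       hi = (X[, odd, drop = FALSE] - X[, even, drop = FALSE]) / sqrt(2))
}

#' One-level 2D Haar decomposition
#'
#' Splits an image into the LL/LH/HL/HH subband quadruple. Odd dimensions
#' are replicate-padded to even on the right/bottom; the padding is recorded
#' in `pad_info` and stripped again by [idwt2_haar()].
#'
#' @param img Numeric matrix, at least 2x2.
#' @return A `subband_set` list with fields `LL`, `LH`, `HL`, `HH` (all of
#'   shape `ceiling(dim(img)/2)`) and `pad_info` (`rows_padded`,
#'   `cols_padded` logicals).
#' @seealso [idwt2_haar()], [wavedec2()]
#' @export
dwt2_haar <- function(img) {
  if (!is.matrix(img) || nrow(img) < 2 || ncol(img) < 2) {
    stop("image must be at least 2x2")
  }
  pad_rows <- nrow(img) %% 2L == 1L
  pad_cols <- ncol(img) %% 2L == 1L
  if (pad_rows) img <- rbind(img, img[nrow(img), ])
  if (pad_cols) img <- cbind(img, img[, ncol(img)])
  cx <- haar_split_cols(img)                       # filter along x
  ly <- haar_split_cols(t(cx$lo))                  # then along y
  hy <- haar_split_cols(t(cx$hi))
  structure(list(LL = t(ly$lo), HL = t(ly$hi),
                 LH = t(hy$lo), HH = t(hy$hi),
                 pad_info = c(rows_padded = pad_rows, cols_padded = pad_cols)),
            class = "subband_set")
}

#' Inverse one-level 2D Haar transform
#'
#' Exact inverse of [dwt2_haar()] (up to floating round-off); replicate
#' padding recorded in `pad_info` is stripped.
#'
#' @param bands A `subband_set`.
#' @return The reconstructed matrix.
#' @export
idwt2_haar <- function(bands) {
  dims <- lapply(bands[c("LL", "LH", "HL", "HH")], dim)
  if (length(unique(dims)) != 1) stop("subband shapes are inconsistent")
  merge_cols <- function(lo, hi) {
    m <- ncol(lo)
    X <- matrix(0, nrow(lo), 2 * m)
    X[, seq(1, 2 * m, 2)] <- (lo + hi) / sqrt(2)
    X[, seq(2, 2 * m, 2)] <- (lo - hi) / sqrt(2)
    X
  }
  lo_x <- t(merge_cols(t(bands$LL), t(bands$HL)))  # undo y split
  hi_x <- t(merge_cols(t(bands$LH), t(bands$HH)))
  img <- merge_cols(lo_x, hi_x)                    # undo x split
  pad <- bands$pad_info
  if (isTRUE(pad[["rows_padded"]])) img <- img[-nrow(img), , drop = FALSE]
  if (isTRUE(pad[["cols_padded"]])) img <- img[, -ncol(img), drop = FALSE]
  img
}

#' Maximum decomposition depth for an image shape
#'
#' The deepest level at which the smaller dimension still holds at least one
#' coefficient for the 2-tap Haar filter: `floor(log2(min(m, n)))`.
#'
#' @param shape Integer `(rows, cols)`, both >= 2.
#' @return Integer depth.
#' @examples
#' max_level(c(299, 299))  # 8
#' @export
max_level <- function(shape) {
  if (any(shape < 2)) stop("dimensions must be at least 2")
  as.integer(floor(log2(min(shape))))
}

#' Multilevel Haar decomposition (Mallat pyramid)
#'
#' Level 1 decomposes the image; level k + 1 decomposes level k's LL band.
#' With `packet = TRUE` the full wavelet-packet tree is built instead: every
#' subband (not only LL) is decomposed at each level, and each pyramid entry
#' holds the list of that level's subband sets.
#'
#' @param img Numeric matrix.
#' @param depth Number of levels, `1 <= depth <= max_level(dim(img))`.
#' @param packet Decompose all four children at each level, not only LL.
#' @return A `decomp_pyramid` list with fields `levels` and `depth`.
#' @export
wavedec2 <- function(img, depth = 2L, packet = FALSE) {
  ml <- max_level(dim(img))
  if (depth < 1 || depth > ml) {
    stop(sprintf("depth must be in [1, %d] for a %dx%d image", ml,
                 nrow(img), ncol(img)))
  }
  levels <- vector("list", depth)
  if (!packet) {
    cur <- img
    for (k in seq_len(depth)) {
      levels[[k]] <- dwt2_haar(cur)
      cur <- levels[[k]]$LL
    }
  } else {
    nodes <- list(img)
    for (k in seq_len(depth)) {
      sets <- lapply(nodes, dwt2_haar)
      levels[[k]] <- if (length(sets) == 1) sets[[1]] else sets
      nodes <- unlist(lapply(sets, function(s) s[c("LL", "LH", "HL", "HH")]),
                      recursive = FALSE)
    }
  }
  structure(list(levels = levels, depth = as.integer(depth), packet = packet),
            class = "decomp_pyramid")
}

#' Extract the deepest low-pass (LL) band, normalized for the network
#'
#' The approximation band of the deepest pyramid level, min/max rescaled to
#' \[0, 1\] so it can feed the classification networks.
#'
#' @param pyr A `decomp_pyramid` from [wavedec2()].
#' @return A gray image matrix of shape `ceiling(dim/2^depth)`.
#' @export
extract_ll <- function(pyr) {
  if (length(pyr$levels) < 1) stop("empty pyramid")
  top <- pyr$levels[[pyr$depth]]
  ll <- if (inherits(top, "subband_set")) top$LL else top[[1]]$LL
  normalize_image(ll)
}

#' Low-pass wavelet features of one image
#'
#' Convenience wrapper: depth-`depth` Mallat decomposition followed by
#' [extract_ll()].
#'
#' @param img Gray image matrix.
#' @param depth Decomposition depth (default 2).
#' @return Normalized LL band.
#' @export
wavelet_features <- function(img, depth = 2L) {
  extract_ll(wavedec2(img, depth = depth))
}
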