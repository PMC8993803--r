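# Canonical image type and I/O. A "gray image" throughout the package is a
# plain numeric matrix with finite values in [0, 1]; 8-bit quantization only
# happens at the PNG boundary, NPY keeps full float precision.

#' Validate a grayscale image matrix
#'
#' Checks the package's image contract: a single-channel numeric matrix with
#' finite intensities inside \[0, 1\].
#'
#' @param img Object to validate.
#' @param arg Name used in error messages.
#' @return The validated matrix, invisibly usable in pipelines.
#' @export
as_gray_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("%s must be a numeric matrix", arg))
  }
  if (any(!is.finite(img))) stop(sprintf("%s contains non-finite values", arg))
  if (min(img) < 0 || max(img) > 1) {
    stop(sprintf("%s has intensities outside [0, 1]; normalize first", arg))
  }
  img
}

#' Rescale a raw-valued 2D grid to \[0, 1\]
#'
#' Affine min/max rescaling. A constant input carries no contrast information
#' and maps to all zeros by convention.
#'
#' @param img Numeric matrix with finite values.
#' @return A gray image matrix in \[0, 1\].
#' @examples
#' normalize_image(matrix(c(0, 255, 127.5, 255), 2, byrow = TRUE))
#' @export
normalize_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img) || length(img) < 1) {
    stop("img must be a non-empty numeric matrix")
  }
  if (any(!is.finite(img))) stop("img contains non-finite values")
  rng <- range(img)
  if (rng[1] == rng[2]) return(array(0, dim(img)))
  (img - rng[1]) / (rng[2] - rng[1])
}

#' Load a grayscale image from PNG or NPY
#'
#' PNG files are read at their stored bit depth and scaled to \[0, 1\];
#' multi-channel PNGs are converted to luminance with the ITU-R 601 weights
#' (0.299, 0.587, 0.114), dropping any alpha channel. NPY files are read
#' losslessly; values outside \[0, 1\] are min/max rescaled.
#'
#' @param path Path to a \code{.png} or \code{.npy} file.
#' @return A gray image matrix.
#' @seealso [save_image()], [normalize_image()]
#' @export
load_image <- function(path) {
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("image file '%s' does not exist", path),
                        class = c("mw_missing_file", "error", "condition")))
  }
  if (file.info(path)$size == 0) {
    stop(errorCondition(sprintf("image file '%s' is empty", path),
                        class = c("mw_unreadable_image", "error", "condition")))
  }
  if (grepl("\\.npy$", path, ignore.case = TRUE)) {
    img <- read_npy(path)
    if (min(img) < 0 || max(img) > 1) img <- normalize_image(img)
    return(img)
  }
  img <- tryCatch(png::readPNG(path), error = function(e) {
    stop(errorCondition(sprintf("cannot decode '%s' as PNG: %s", path,
                                conditionMessage(e)),
                        class = c("mw_unreadable_image", "error", "condition")))
  })
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    img <- if (nc >= 3L) {
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      img[, , 1]
    }
  }
  pmin(pmax(img, 0), 1)
}

#' Save a grayscale image
#'
#' \code{.png} paths write 8-bit grayscale PNG (round-trips within 1/255 per
#' pixel); \code{.npy} paths write lossless float64.
#'
#' @param img Gray image matrix in \[0, 1\].
#' @param path Output path ending in \code{.png} or \code{.npy}.
#' @return Invisibly, `path`.
#' @export
save_image <- function(img, path) {
  img <- as_gray_image(img)
  if (!dir.exists(dirname(path))) {
    stop(sprintf("directory '%s' does not exist", dirname(path)))
  }
  if (grepl("\\.npy$", path, ignore.case = TRUE)) {
    write_npy(img, path)
  } else {
    png::writePNG(img, path)
  }
  invisible(path)
}

#' Construct a labeled sample
#'
#' Couples an image with its abnormality class label and provenance
#' (\code{real} data, the synthetic generator, or a GAN).
#'
#' @param image Gray image matrix.
#' @param label Class label, one of `class_set`.
#' @param class_set Character vector of allowed labels.
#' @param source One of `"real"`, `"synthetic"`, `"gan"`.
#' @return A `labeled_sample` list with fields `image`, `label`, `source`.
#' @export
labeled_sample <- function(image, label, class_set = mammo_classes(),
                           source = c("real", "synthetic", "gan")) {
  source <- match.arg(source)
  if (!label %in% class_set) {
    stop(sprintf("label '%s' is not in the class set {%s}", label,
                 paste(class_set, collapse = ", ")))
  }
  structure(list(image = as_gray_image(image), label = label, source = source),
            class = "labeled_sample")
}

#' Mammographic abnormality class sets
#'
#' The five-class set is normal (N), benign calcification (BC), benign mass
#' (BM), calcification (CALC) and mass (M); the extended seven-class set adds
#' architectural distortion (AD) and asymmetry (ASYM).
#'
#' @param extended Include AD and ASYM.
#' @return Character vector of class labels.
#' @export
mammo_classes <- function(extended = FALSE) {
  base <- c("N", "BC", "BM", "CALC", "M")
  if (extended) c(base, "AD", "ASYM") else base
}
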