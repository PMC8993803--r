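# The cosine-Gaussian (real Morlet-type) activation that replaces ReLU in
# the wavelet CNN:
#   psi(x)      = cos(beta * x) * exp(-x^2 / 2)
#   psi'(x)     = -beta * sin(beta * x) * exp(-x^2 / 2)
#                 - x * cos(beta * x) * exp(-x^2 / 2)
# The Gaussian envelope bounds |psi| by exp(-x^2/2) <= 1 and drives
# activations to zero far from the origin; beta shifts the oscillation
# frequency and is a hyperparameter (not learned).

#' Wavelet activation parameters
#'
#' @param beta Positive finite oscillation frequency (default 0.5).
#' @return An `activation_params` list.
#' @export
activation_params <- function(beta = 0.5) {
  stopifnot(is.numeric(beta), length(beta) == 1, is.finite(beta), beta > 0)
  structure(list(beta = beta), class = "activation_params")
}

#' Wavelet activation function
#'
#' Elementwise `cos(beta * x) * exp(-x^2/2)`. For |x| > 40 the result is
#' exactly 0 (the envelope underflows long before that).
#'
#' @param x Numeric scalar, vector, matrix or array; must be finite.
#' @param params An [activation_params()].
#' @return Same shape as `x`.
#' @examples
#' psi(0)        # 1
#' psi(pi)       # 0 up to floating error (cos(pi/2) = 0 at beta = 0.5)
#' @export
psi <- function(x, params = activation_params()) {
  if (any(!is.finite(x))) stop("psi received non-finite input")
  out <- cos(params$beta * x) * exp(-x^2 / 2)
  out[abs(x) > 40] <- 0
  out
}

#' Analytic derivative of the wavelet activation
#'
#' `-beta*sin(beta*x)*exp(-x^2/2) - x*cos(beta*x)*exp(-x^2/2)`, used for
#' backpropagation through wavelet-activated layers.
#'
#' @inheritParams psi
#' @return Same shape as `x`.
#' @export
psi_grad <- function(x, params = activation_params()) {
  if (any(!is.finite(x))) stop("psi_grad received non-finite input")
  env <- exp(-x^2 / 2)
  out <- -params$beta * sin(params$beta * x) * env - x * cos(params$beta * x) * env
  out[abs(x) > 40] <- 0
  out
}

#' Package the wavelet function as a pluggable activation
#'
#' Returns the activation contract the network builders consume: `forward`
#' applies [psi()]; `backward` multiplies an upstream gradient by
#' [psi_grad()] evaluated at the forward input (chain rule). The activation
#' has no trainable parameters.
#'
#' @param params An [activation_params()].
#' @return An `activation_fn` list with fields `name`, `forward`, `backward`.
#' @export
wavelet_activation <- function(params = activation_params()) {
  structure(list(
    name = "wavelet",
    forward = function(x) psi(x, params),
    backward = function(x, upstream) upstream * psi_grad(x, params)
  ), class = "activation_fn")
}

#' ReLU packaged under the same activation contract
#'
#' @return An `activation_fn` list.
#' @export
relu_activation <- function() {
  structure(list(
    name = "relu",
    forward = function(x) pmax(x, 0),
    backward = function(x, upstream) upstream * (x > 0)
  ), class = "activation_fn")
}
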