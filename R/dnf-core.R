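#' @useDynLib dnfreach, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif
NULL

#' Discretized feature lattice
#'
#' A lattice samples one feature dimension of a dynamic neural field (DNF)
#' uniformly. The spatial dimension of the model is circular (directions in
#' degrees, extent 360), the context dimension is bounded (abstract units).
#'
#' @param n Number of samples (positive integer).
#' @param extent Extent of the dimension (360 for the circular spatial
#'   dimension; defaults to `n` abstract units for a bounded dimension).
#' @param circular Logical; circular (wrap-around) boundary?
#' @param name Optional dimension label.
#' @return An object of class `dnf_lattice` with fields `n`, `extent`,
#'   `dx` (sample spacing), `pos` (sample positions) and `circular`.
#' @examples
#' lat <- make_lattice(180, 360, circular = TRUE)
#' lat$dx  # 2 degrees
#' @export
make_lattice <- function(n, extent = n, circular = FALSE, name = NULL) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 2, n == round(n), extent > 0)
  dx <- extent / n
  pos <- if (circular) (seq_len(n) - 1) * dx else (seq_len(n) - 0.5) * dx
  structure(list(n = as.integer(n), extent = extent, dx = dx, pos = pos,
                 circular = isTRUE(circular), name = name),
            class = "dnf_lattice")
}

#' Circular distance between directions (degrees)
#'
#' @param a,b Directions in degrees (recycled).
#' @return Absolute angular distance in `[0, 180]`.
#' @examples
#' circ_dist(350, 10)  # 20
#' @export
circ_dist <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

#' Wrap directions to [0, 360)
#' @param a Directions in degrees.
#' @export
wrap_dir <- function(a) a %% 360

#' Field dynamics parameters
#'
#' Leaky-integrator parameters shared by fields and node groups: time
#' constant `tau` (model time units), negative resting level `h`
#' (activation units), noise amplitude `q` (activation units per sqrt time
#' unit) and sigmoid steepness `beta` (threshold fixed at 0).
#'
#' @param tau Time constant, > 0.
#' @param h Resting level, < 0.
#' @param q Noise amplitude, >= 0.
#' @param beta Sigmoid steepness, > 0.
#' @return A `dnf_params` list.
#' @export
field_params <- function(tau = 10, h = -2, q = 0, beta = 4) {
  if (!(is.numeric(tau) && tau > 0)) stop("tau must be > 0")
  if (!(is.numeric(h) && h < 0)) stop("resting level h must be negative")
  if (!(is.numeric(q) && q >= 0)) stop("noise amplitude q must be >= 0")
  if (!(is.numeric(beta) && beta > 0)) stop("beta must be > 0")
  structure(list(tau = tau, h = h, q = q, beta = beta), class = "dnf_params")
}

#' Sigmoid output nonlinearity
#'
#' Logistic output function of a DNF: `f(u) = 1 / (1 + exp(-beta * u))`.
#' Output is near zero for low activation, rises around the soft threshold
#' at zero and saturates at one.
#'
#' @param u Activation array (any shape).
#' @param beta Steepness, > 0.
#' @return Array of the same shape with values in (0, 1).
#' @examples
#' sigmoid_output(0, 4)   # 0.5
#' @export
sigmoid_output <- function(u, beta) {
  if (!all(is.finite(u))) stop("non-finite activation values")
  stopifnot(beta > 0)
  1 / (1 + exp(-beta * u))
}

#' Lateral interaction kernel
#'
#' Difference-of-Gaussians kernel with an optional constant (global)
#' inhibitory component: local excitation of amplitude `a_exc` and width
#' `sigma_exc`, surround inhibition of amplitude `a_inh` and width
#' `sigma_inh` (`sigma_inh > sigma_exc` when both are local), and a
#' position-independent inhibition `g_inh` subtracted at every offset.
#' Widths are in the units of the lattice dimension (degrees for the
#' spatial dimension).
#'
#' @param a_exc,sigma_exc Excitatory amplitude and Gaussian width.
#' @param a_inh,sigma_inh Local inhibitory amplitude and width.
#' @param g_inh Global (constant) inhibition amplitude.
#' @return A `dnf_kernel_params` list.
#' @export
kernel_params <- function(a_exc = 0, sigma_exc = 1, a_inh = 0, sigma_inh = 2,
                          g_inh = 0) {
  stopifnot(sigma_exc > 0, sigma_inh > 0)
  if (a_exc > 0 && a_inh > 0 && sigma_inh <= sigma_exc)
    stop("inhibitory width must exceed excitatory width for local surround inhibition")
  structure(list(a_exc = a_exc, sigma_exc = sigma_exc, a_inh = a_inh,
                 sigma_inh = sigma_inh, g_inh = g_inh),
            class = "dnf_kernel_params")
}

#' Sample an interaction kernel on a lattice
#'
#' Evaluates the kernel at every lattice offset. On a circular lattice the
#' wrapped distance is used, so the kernel value at offset between 350 and
#' 10 degrees equals its value at 20 degrees.
#'
#' @param lattice A [make_lattice()] lattice.
#' @param kp A [kernel_params()] object.
#' @return Numeric vector of length `lattice$n`: kernel values at offsets
#'   `0, dx, 2 dx, ...` (wrapped for circular lattices).
#' @export
build_kernel <- function(lattice, kp) {
  offs <- (seq_len(lattice$n) - 1) * lattice$dx
  d <- if (lattice$circular) pmin(offs, lattice$extent - offs) else offs
  if (!lattice$circular && kp$a_exc > 0 && 2 * kp$sigma_exc > lattice$extent)
    stop("kernel wider than lattice extent on a bounded dimension")
  k <- kp$a_exc * exp(-d^2 / (2 * kp$sigma_exc^2)) -
    kp$a_inh * exp(-d^2 / (2 * kp$sigma_inh^2)) - kp$g_inh
  k
}

# Gaussian profile over lattice offsets, normalized to unit sum, so that a
# gain expressed as integrated connection strength is resolution-independent.
unit_profile <- function(lattice, sigma) {
  offs <- (seq_len(lattice$n) - 1) * lattice$dx
  d <- if (lattice$circular) pmin(offs, lattice$extent - offs) else offs
  g <- exp(-d^2 / (2 * sigma^2))
  g / sum(g)
}

# Circular convolution of x with a kernel sampled at offsets 0, dx, ...
# (kernel symmetric about 0 by construction). Direct O(N^2) is avoided via FFT
# for speed in the reference path; the C++ path uses truncated direct sums.
circ_conv <- function(x, k) {
  n <- length(x)
  stopifnot(length(k) == n)
  Re(stats::fft(stats::fft(x) * stats::fft(k), inverse = TRUE)) / n
}

# Bounded (zero-padded) convolution along a non-circular dimension.
bounded_conv <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    js <- seq_len(n)
    off <- abs(js - i) + 1L
    out[i] <- sum(k[off] * x[js])
  }
  out
}

#' Field state
#'
#' Bundles a lattice (or a pair of lattices for the 2-D association field),
#' dynamics parameters, an interaction kernel configuration and the current
#' activation. Activation is initialized at the resting level `h`.
#'
#' @param lattice A lattice, or a list of two lattices for a 2-D field.
#' @param params A [field_params()] object.
#' @param kernel Either a [kernel_params()] object (1-D) or a list with one
#'   `kernel_params` per dimension plus a shared `g_inh` for 2-D fields.
#' @return A `dnf_field` object with elements `lattice`, `params`,
#'   `kernel`, `u` (activation) and `s` (current external input).
#' @export
field_state <- function(lattice, params, kernel) {
  two_d <- !inherits(lattice, "dnf_lattice")
  if (two_d) stopifnot(length(lattice) == 2)
  dims <- if (two_d) c(lattice[[1]]$n, lattice[[2]]$n) else lattice$n
  u <- array(params$h, dim = dims)
  structure(list(lattice = lattice, params = params, kernel = kernel,
                 u = u, s = array(0, dim = dims), two_d = two_d),
            class = "dnf_field")
}

#' Lateral interaction input of a field
#'
#' Convolves the sigmoid output of the field with its interaction kernel.
#' For 1-D circular fields this is a circular convolution; the 2-D
#' association field uses a separable product kernel (circular along the
#' spatial dimension, zero-padded along the bounded context dimension) plus
#' global inhibition proportional to the mean output of the whole field.
#'
#' @param state A [field_state()] object.
#' @return Array of lateral input, same shape as `state$u`.
#' @export
lateral_input <- function(state) {
  f <- sigmoid_output(state$u, state$params$beta)
  if (!state$two_d) {
    k <- build_kernel(state$lattice, state$kernel)
    return(circ_conv(f, k))
  }
  # 2-D separable kernel: product of per-dimension unit-sum Gaussian
  # profiles scaled by a_exc, plus global inhibition ~ mean output.
  kk <- state$kernel
  px <- unit_profile(state$lattice[[1]], kk$sigma_x)
  py <- unit_profile(state$lattice[[2]], kk$sigma_y)
  ex <- apply(f, 2, function(col) circ_conv(col, px))
  ex <- t(apply(ex, 1, function(row) bounded_conv(row, py)))
  kk$a_exc * ex - kk$g_inh * mean(f)
}

#' One Euler integration step of a field
#'
#' Stochastic explicit Euler update
#' `u <- u + (dt/tau) * (-u + h + s + lateral) + q * sqrt(dt) * xi`
#' with `xi` i.i.d. standard normal per sample, so that the accumulated
#' noise variance per unit model time is independent of `dt`.
#'
#' @param state A [field_state()].
#' @param s External input array (same shape as `state$u`), or a scalar.
#' @param dt Time step, `0 < dt << tau`.
#' @return The updated `dnf_field`.
#' @export
field_step <- function(state, s = 0, dt = 1) {
  stopifnot(dt > 0, dt <= state$params$tau)
  if (length(s) == 1) s <- array(s, dim = dim(state$u) %||% length(state$u))
  if (!all(is.finite(s))) stop("non-finite input")
  if (!identical(length(s), length(state$u))) stop("input shape mismatch")
  p <- state$params
  lat <- lateral_input(state)
  noise <- if (p$q > 0) p$q * sqrt(dt) * array(rnorm(length(state$u)),
                                               dim = dim(state$u)) else 0
  state$u <- state$u + (dt / p$tau) * (-state$u + p$h + s + lat) + noise
  state$s <- s
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group of discrete dynamic nodes
#'
#' Nodes (used for the contextual cue input) follow the same leaky
#' integrator dynamics as fields, with an interaction matrix of
#' self-excitation on the diagonal and mutual inhibition off the diagonal.
#' With sufficient self-excitation an externally activated node latches:
#' it stays active after input removal and suppresses the other nodes.
#'
#' @param n Number of nodes.
#' @param params A [field_params()] object.
#' @param w_self Self-excitation strength.
#' @param w_mut Mutual inhibition strength (>= 0).
#' @return A `dnf_nodes` object.
#' @export
node_group <- function(n, params, w_self, w_mut) {
  stopifnot(n >= 1, w_mut >= 0)
  structure(list(n = as.integer(n), params = params, w_self = w_self,
                 w_mut = w_mut, u = rep(params$h, n)), class = "dnf_nodes")
}

#' One Euler step of a node group
#'
#' @param nodes A [node_group()].
#' @param inputs External input per node (scalar or length-n vector).
#' @param dt Time step.
#' @return Updated `dnf_nodes`.
#' @export
node_step <- function(nodes, inputs = 0, dt = 1) {
  p <- nodes$params
  f <- sigmoid_output(nodes$u, p$beta)
  lat <- nodes$w_self * f - nodes$w_mut * (sum(f) - f)
  noise <- if (p$q > 0) p$q * sqrt(dt) * rnorm(nodes$n) else 0
  nodes$u <- nodes$u + (dt / p$tau) * (-nodes$u + p$h + inputs + lat) + noise
  nodes
}

# Gaussian input bump over a circular lattice (stimulus model: amplitude =
# salience * field input gain, width sigma in degrees).
input_bump <- function(lattice, direction, amplitude, sigma) {
  d <- circ_dist(lattice$pos, direction)
  amplitude * exp(-d^2 / (2 * sigma^2))
}
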