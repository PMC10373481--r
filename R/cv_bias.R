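#' Evaluate the LDA coordinate for one configuration
#'
#' Single-frame equivalent of [project_cv()], exposed separately for
#' per-step use during dynamics.
#'
#' @param frame `N x 3` coordinate matrix (raw, unaligned).
#' @param model A [train_poslda()] model.
#' @return Scalar coordinate value `l` (Angstrom).
#' @export
compute_cv <- function(frame, model) {
  model <- check_model(model)
  frame <- check_frame(frame)
  if (nrow(frame) != model$meta$n_particles)
    stop("frame and model have different particle counts", call. = FALSE)
  cpp_cv(frame, model$ref$mean, model$ref$precision, model$v)
}

#' Numerical gradient of the LDA coordinate
#'
#' Central finite differences of [compute_cv()] with respect to every raw
#' coordinate.  The optimal rotation depends implicitly on the positions, so
#' the gradient is not simply the coefficient vector away from the reference;
#' the finite difference captures that coupling.  Analytic differentiation
#' through the SVD is deliberately not attempted.
#'
#' @inheritParams compute_cv
#' @param step Finite-difference step (Angstrom).
#' @param check If `TRUE`, recompute at `step / 2` and warn when the two
#'   gradients differ by more than 1\% (a sign the step is too large).
#' @return `N x 3` gradient matrix.
#' @export
cv_gradient <- function(frame, model, step = 1e-4, check = FALSE) {
  model <- check_model(model)
  frame <- check_frame(frame)
  stopifnot(step > 0)
  G <- cpp_cv_grad(frame, model$ref$mean, model$ref$precision, model$v, step)
  if (check) {
    G2 <- cpp_cv_grad(frame, model$ref$mean, model$ref$precision, model$v, step / 2)
    rel <- max(abs(G - G2)) / max(max(abs(G2)), 1e-12)
    if (rel > 0.01)
      warning(sprintf("gradient changes by %.2g%% when halving the step; reduce `step`",
                      100 * rel))
  }
  G
}

new_hills <- function() {
  tibble::tibble(time = integer(0), center = numeric(0), height = numeric(0),
                 width = numeric(0))
}

#' Well-tempered metadynamics: deposit one hill
#'
#' Appends a Gaussian hill at the current CV value `Q`.  The deposited height
#' shrinks with the bias already accumulated there,
#' \eqn{h \exp[-V(Q, t) / k_B \Delta T]} with
#' \eqn{\Delta T = (\gamma - 1) T}, so the bias converges towards
#' \eqn{(1 - 1/\gamma)} of the underlying free energy.
#'
#' @param hills Tibble of hills (columns `time`, `center`, `height`,
#'   `width`), e.g. from a previous call; `NULL` starts an empty record.
#' @param Q Current CV value.
#' @param height Initial hill height `h` (kcal/mol).
#' @param sigma Gaussian width (CV units).  A practical default is one third
#'   of the CV's standard deviation in the starting basin.
#' @param gamma Bias factor \eqn{\gamma = (T + \Delta T)/T > 1}.
#' @param temperature Temperature (K).
#' @param time Step index recorded with the hill.
#' @return The extended hills tibble.
#' @export
wtmetad_update <- function(hills, Q, height, sigma, gamma, temperature = 300,
                           time = NA_integer_) {
  if (is.null(hills)) hills <- new_hills()
  stopifnot(height > 0, sigma > 0)
  if (gamma <= 1) stop("gamma must be > 1", call. = FALSE)
  V <- wtmetad_bias(hills, Q)
  h_t <- height * exp(-V / (kB * (gamma - 1) * temperature))
  dplyr::bind_rows(hills, tibble::tibble(time = as.integer(time), center = Q,
                                         height = h_t, width = sigma))
}

#' Well-tempered metadynamics bias at given CV values
#'
#' \eqn{V(Q) = \sum_i h_i \exp[-(Q - Q_i)^2 / (2\sigma_i^2)]}.
#'
#' @param hills Hills tibble (see [wtmetad_update()]); `NULL` or empty gives 0.
#' @param Q CV value(s).
#' @return Bias energies (kcal/mol), same length as `Q`.
#' @export
wtmetad_bias <- function(hills, Q) {
  if (is.null(hills) || nrow(hills) == 0) return(rep(0, length(Q)))
  vapply(Q, function(q)
    sum(hills$height * exp(-(q - hills$center)^2 / (2 * hills$width^2))),
    numeric(1))
}

#' On-the-fly probability enhanced sampling (OPES) state
#'
#' Creates an empty OPES bias state: a kernel density estimate of the CV
#' distribution that is updated on the fly, with the applied bias capped at
#' `deltaE`.  The regularization constant is
#' \eqn{\epsilon = \exp[-\Delta E / ((1 - 1/\gamma) k_B T)]}, which makes the
#' cap exact for unsampled regions; because the kernel density itself can
#' exceed the uniform level, the applied (min-shifted) bias is additionally
#' clipped at `deltaE`.
#'
#' @param gamma Bias factor (> 1).
#' @param deltaE Bias cap (kcal/mol, > 0).
#' @param sigma Kernel bandwidth (CV units).
#' @param temperature Temperature (K).
#' @param range Length-2 CV interval over which the density is normalized.
#' @param ngrid Grid points for the normalization integral.
#' @return An object of class `opes_state`.
#' @export
opes_state <- function(gamma, deltaE, sigma, temperature = 300,
                       range = c(-1, 1), ngrid = 500) {
  if (gamma <= 1) stop("gamma must be > 1", call. = FALSE)
  if (deltaE <= 0) stop("deltaE must be > 0", call. = FALSE)
  stopifnot(sigma > 0, length(range) == 2, range[2] > range[1])
  eps <- exp(-deltaE / ((1 - 1 / gamma) * kB * temperature))
  structure(list(kernels = tibble::tibble(center = numeric(0), weight = numeric(0),
                                          width = numeric(0)),
                 gamma = gamma, deltaE = deltaE, sigma = sigma,
                 temperature = temperature, epsilon = eps, sum_w = 0,
                 range = range, ngrid = ngrid, Z = 1),
            class = "opes_state")
}

opes_density <- function(state, Q) {
  if (state$sum_w <= 0) return(rep(0, length(Q)))
  k <- state$kernels
  G <- exp(-outer(k$center, Q, "-")^2 / (2 * k$width^2))
  colSums(k$weight * G) / state$sum_w
}

opes_Z <- function(state) {
  q <- seq(state$range[1], state$range[2], length.out = state$ngrid)
  max(mean(opes_density(state, q)) * diff(state$range), 1e-300)
}

#' OPES: incorporate one CV observation
#'
#' Adds a kernel at `Q` with the on-the-fly reweighting factor
#' \eqn{e^{V(Q)/k_B T}}; kernels closer than half a bandwidth are merged
#' (weighted mean center, summed weight) to bound memory.  The normalization
#' `Z` is refreshed by integrating the density over the state's CV range.
#'
#' @param state An [opes_state()].
#' @param Q Observed CV value.
#' @return The updated `opes_state`.
#' @export
opes_update <- function(state, Q) {
  stopifnot(inherits(state, "opes_state"))
  w <- exp(opes_bias(state, Q) / (kB * state$temperature))
  k <- state$kernels
  if (nrow(k) > 0) {
    d <- abs(k$center - Q)
    i <- which.min(d)
  }
  if (nrow(k) > 0 && d[i] < state$sigma / 2) {
    wn <- k$weight[i] + w
    k$center[i] <- (k$weight[i] * k$center[i] + w * Q) / wn
    k$weight[i] <- wn
  } else {
    k <- dplyr::bind_rows(k, tibble::tibble(center = Q, weight = w,
                                            width = state$sigma))
  }
  state$kernels <- k
  state$sum_w <- state$sum_w + w
  state$Z <- opes_Z(state)
  state
}

#' OPES bias at given CV values
#'
#' \eqn{V(Q) = (1 - 1/\gamma) k_B T [\ln(P_t(Q)/Z_t + \epsilon) - \ln \epsilon]},
#' min-shifted so unsampled regions sit at zero and clipped at the cap
#' `deltaE`.
#'
#' @param state An [opes_state()].
#' @param Q CV value(s).
#' @return Bias energies in `[0, deltaE]` (kcal/mol).
#' @export
opes_bias <- function(state, Q) {
  stopifnot(inherits(state, "opes_state"))
  if (state$sum_w <= 0) return(rep(0, length(Q)))
  p <- opes_density(state, Q)
  v <- (1 - 1 / state$gamma) * kB * state$temperature *
    (log(p / state$Z + state$epsilon) - log(state$epsilon))
  pmin(pmax(v, 0), state$deltaE)
}

#' Quadratic wall potential on a CV
#'
#' Zero inside `[lower, upper]`; \eqn{\kappa (Q - b)^2} outside the nearer
#' bound `b`, with the matching analytic derivative.
#'
#' @param Q CV value(s).
#' @param lower,upper Wall positions (CV units), `lower < upper`.
#' @param kappa Wall coefficient (kcal/mol per CV unit squared, > 0).
#' @return Tibble with columns `Q`, `energy`, `deriv`.
#' @export
wall_potential <- function(Q, lower, upper, kappa) {
  stopifnot(lower < upper, kappa > 0)
  d <- pmax(Q - upper, 0) + pmin(Q - lower, 0)
  tibble::tibble(Q = Q, energy = kappa * d^2, deriv = 2 * kappa * d)
}

#' Free energy surface from an accumulated bias
#'
#' Asymptotically the metadynamics bias tends to \eqn{-(1 - 1/\gamma) F(Q)},
#' so \eqn{F(Q) = -\gamma/(\gamma - 1) V(Q)} up to a constant; the same
#' relation applies to the OPES bias (the \eqn{\epsilon} floor makes it
#' approximate in barely-sampled regions).  The result is shifted so its
#' minimum is zero.
#'
#' @param grid_q CV grid.
#' @param bias Bias energies on the grid (kcal/mol).
#' @param gamma Bias factor used during sampling.
#' @return Tibble of class `fes_result` with columns `q` and `F`.
#' @export
fes_from_bias <- function(grid_q, bias, gamma) {
  stopifnot(length(grid_q) == length(bias), gamma > 1)
  F <- -gamma / (gamma - 1) * bias
  out <- tibble::tibble(q = grid_q, F = F - min(F))
  class(out) <- c("fes_result", class(out))
  out
}
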