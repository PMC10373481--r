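#' Shape reference: mean structure with particle covariance
#'
#' Bundles the mean structure \eqn{\mu} (`N x 3`, Angstrom) and the `N x N`
#' particle covariance \eqn{\Sigma_N} of a state in size-and-shape space.  The
#' full 3N-dimensional covariance is the Kronecker product
#' \eqn{\Sigma_N \otimes I_3}: the same particle-particle covariance acts
#' identically and independently on x, y and z.  Because frames are centered,
#' \eqn{\Sigma_N} is singular by construction (the ones vector is in its null
#' space), so the stored precision is a rank-truncated pseudo-inverse:
#' eigenvalues below `tau` times the largest are dropped and the retained rank
#' is recorded.
#'
#' @param mean `N x 3` mean structure; centered internally.
#' @param cov `N x N` symmetric positive semi-definite particle covariance
#'   (Angstrom^2).
#' @param weight Mixture weight of the state, in (0, 1].
#' @param tau Relative eigenvalue cutoff for the pseudo-inverse.
#' @return An object of class `shape_ref` with elements `mean`, `cov`,
#'   `precision`, `rank`, `weight`.
#' @export
shape_ref <- function(mean, cov, weight = 1, tau = 1e-10) {
  mean <- check_frame(mean)
  N <- nrow(mean)
  stopifnot(is.matrix(cov), nrow(cov) == N, ncol(cov) == N)
  if (max(abs(cov - t(cov))) > 1e-10 * max(1, max(abs(cov))))
    stop("covariance must be symmetric", call. = FALSE)
  if (weight <= 0 || weight > 1) stop("weight must be in (0, 1]", call. = FALSE)
  cov <- 0.5 * (cov + t(cov))
  p <- cpp_pinv_trunc(cov, tau)
  structure(
    list(mean = sweep(mean, 2, colMeans(mean)), cov = cov,
         precision = p$precision, rank = p$rank, weight = weight, tau = tau),
    class = "shape_ref"
  )
}

#' @export
print.shape_ref <- function(x, ...) {
  cat(sprintf("<shape reference: %d particles, covariance rank %d, weight %.3f>\n",
              nrow(x$mean), x$rank, x$weight))
  invisible(x)
}

check_ref <- function(ref) {
  if (!inherits(ref, "shape_ref")) stop("expected a shape_ref", call. = FALSE)
  ref
}

#' Mahalanobis-optimal rigid-body transformation onto a reference
#'
#' Finds the translation and proper rotation minimizing the Mahalanobis
#' distance between a frame and the reference mean under the reference's
#' particle precision (a precision-weighted Kabsch problem, solved in closed
#' form by SVD of the weighted cross-covariance with reflection correction).
#'
#' @param frame `N x 3` coordinate matrix.
#' @param ref A [shape_ref()].
#' @return A list of class `rigid_motion` with `translation` (length 3; the
#'   shift that centers the frame) and `rotation` (proper orthogonal 3 x 3,
#'   applied on the right to the centered positions).
#' @export
optimal_rotation <- function(frame, ref) {
  frame <- check_frame(frame)
  ref <- check_ref(ref)
  if (nrow(frame) != nrow(ref$mean))
    stop("frame and reference have different particle counts", call. = FALSE)
  centroid <- colMeans(frame)
  Xc <- sweep(frame, 2, centroid)
  sv <- svd(Xc)$d
  if (sv[2] < 1e-12 * max(sv[1], 1)) {
    warning("degenerate (collinear or zero-variance) frame; using identity rotation")
    R <- diag(3)
  } else {
    R <- cpp_kabsch(Xc, ref$mean, ref$precision)
  }
  structure(list(translation = -centroid, rotation = R), class = "rigid_motion")
}

#' Map a frame to its size-and-shape-space representative
#'
#' Centers a frame and applies the Mahalanobis-optimal rotation towards the
#' reference, i.e. picks the representative of the frame's equivalence class
#' under rigid motion.  Idempotent and invariant to any rigid motion of the
#' input.
#'
#' @inheritParams optimal_rotation
#' @return The aligned `N x 3` matrix.
#' @export
align_frame <- function(frame, ref) {
  g <- optimal_rotation(frame, ref)
  frame <- check_frame(frame)
  sweep(frame, 2, -g$translation) %*% g$rotation
}

#' Align every frame of a trajectory to a reference
#'
#' @param traj An `ldacv_traj` (or coercible object).
#' @param ref A [shape_ref()].
#' @return An aligned `ldacv_traj`.
#' @export
align_traj <- function(traj, ref) {
  traj <- as_traj(traj)
  ref <- check_ref(ref)
  if (dim(traj)[1] != nrow(ref$mean))
    stop("trajectory and reference have different particle counts", call. = FALSE)
  as_traj(cpp_align_traj(unclass(traj), ref$mean, ref$precision),
          ids = attr(traj, "ids"))
}

#' Squared Mahalanobis distance of an aligned frame to a reference
#'
#' Computes \eqn{\sum_{d \in xyz} (x_d - \mu_d)^T \Sigma_N^{+} (x_d - \mu_d)}
#' with the rank-truncated pseudo-inverse.  The frame must already be aligned
#' (zero centroid); its expectation for frames drawn from the reference is
#' `3 * rank`.
#'
#' @inheritParams optimal_rotation
#' @return Non-negative scalar.
#' @export
mahalanobis_sq <- function(frame, ref) {
  frame <- check_frame(frame)
  ref <- check_ref(ref)
  if (nrow(frame) != nrow(ref$mean))
    stop("frame and reference have different particle counts", call. = FALSE)
  if (sqrt(sum(colMeans(frame)^2)) > 1e-6)
    stop("frame is not centered; align it first", call. = FALSE)
  cpp_mahal_sq(frame, ref$mean, ref$precision)
}

#' Iterative mean and covariance estimation in size-and-shape space
#'
#' Alternates (i) aligning every frame to the current mean and precision and
#' (ii) re-estimating the mean as the frame average and the particle
#' covariance as the positional covariance averaged over the three Cartesian
#' dimensions, until the largest mean-coordinate change drops below `tol`.
#' The first iteration uses an identity covariance, i.e. a plain Kabsch
#' alignment to the centered first frame, which also fixes the (otherwise
#' arbitrary) global orientation of the result.
#'
#' @param traj Trajectory with at least 2 frames.
#' @param tol Convergence tolerance on the max mean-coordinate change
#'   (Angstrom).
#' @param max_iter Iteration cap; non-convergence gives a warning, and the
#'   last iterate is returned.
#' @param tau Relative eigenvalue cutoff for the covariance pseudo-inverse.
#' @return A [shape_ref()] with attributes `aligned` (the trajectory aligned
#'   to the converged reference), `iterations`, `converged`, and `objective`
#'   (per-iteration negative log-likelihood per frame, up to constants).
#' @export
iterative_mean_cov <- function(traj, tol = 1e-8, max_iter = 200, tau = 1e-10) {
  traj <- as_traj(traj)
  if (dim(traj)[3] < 2) stop("need at least 2 frames", call. = FALSE)
  fit <- cpp_iterative_mean_cov(unclass(traj), tol, max_iter, tau)
  if (!fit$converged)
    warning(sprintf(
      "iterative alignment did not converge in %d iterations (last change %.3g)",
      max_iter, fit$delta))
  ref <- shape_ref(fit$mean, fit$cov, tau = tau)
  attr(ref, "aligned") <- as_traj(fit$aligned, ids = attr(traj, "ids"))
  attr(ref, "iterations") <- fit$iterations
  attr(ref, "converged") <- fit$converged
  attr(ref, "objective") <- fit$objective
  ref
}
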