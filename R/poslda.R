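flatten_traj <- function(traj) {
  # frames as rows, coordinates stacked column-major (all x, all y, all z)
  d <- dim(traj)
  t(matrix(unclass(traj), d[1] * 3, d[3]))
}

#' Pool two states and align them to a single global reference
#'
#' Position-LDA requires every frame to live in one common size-and-shape
#' frame.  Aligning each cluster to its own mean would give scatter matrices
#' with incompatible null spaces, and aligning to one cluster is asymmetric;
#' aligning the amalgamated two-state trajectory to its own iteratively
#' estimated global mean and covariance avoids both problems.
#'
#' @param traj Full trajectory.
#' @param labels Per-frame integer labels (a `state_assignment` or a vector).
#' @param states Length-2 vector: the two state labels to pool (A first).
#' @param tol,max_iter Passed to [iterative_mean_cov()].
#' @return A list with `aligned` (pooled aligned trajectory), `ref` (global
#'   [shape_ref()]), and `labels` (labels of the pooled frames).
#' @export
global_align <- function(traj, labels, states, tol = 1e-8, max_iter = 200) {
  traj <- as_traj(traj)
  if (inherits(labels, "state_assignment")) labels <- labels$labels
  stopifnot(length(labels) == dim(traj)[3], length(states) == 2)
  keep <- which(labels %in% states)
  if (!all(states %in% labels[keep]))
    stop(sprintf("state %s has no frames",
                 paste(setdiff(states, labels), collapse = ",")), call. = FALSE)
  pooled <- subset_frames(traj, keep)
  ref <- iterative_mean_cov(pooled, tol = tol, max_iter = max_iter)
  aligned <- attr(ref, "aligned")
  attr(ref, "aligned") <- NULL
  list(aligned = aligned, ref = ref, labels = labels[keep])
}

#' Within- and between-cluster scatter matrices on positions
#'
#' For frames aligned to a common global reference, computes in the full
#' 3N-dimensional coordinate space the within-cluster scatter
#' \eqn{S_w = \sum_i \sum_{t \in i} (x_t - \mu_i)(x_t - \mu_i)^T} and the
#' population-weighted between-cluster scatter
#' \eqn{S_b = \sum_i n_i (\mu_i - \mu)(\mu_i - \mu)^T}, so that
#' \eqn{S_w + S_b} equals the total scatter of the pooled data.  Dense 3N
#' storage is exact and comfortable up to a few hundred particles.
#'
#' @param aligned Aligned trajectory (e.g. from [global_align()]).
#' @param labels Per-frame labels, exactly two distinct values.
#' @param population_weighted If `TRUE` (default), each cluster's
#'   between-scatter term carries its population `n_i`, which is what makes
#'   the total-scatter decomposition hold; `FALSE` drops the `n_i` factors
#'   (for two classes this only rescales, leaving the discriminant
#'   direction unchanged at equal populations).
#' @return An object of class `scatter_pair`: list with `S_w`, `S_b`,
#'   `cluster_means` (named list of `N x 3`), `global_mean`, `n` (per-cluster
#'   counts), `states`.
#' @export
scatter_matrices <- function(aligned, labels, population_weighted = TRUE) {
  aligned <- as_traj(aligned)
  if (inherits(labels, "state_assignment")) labels <- labels$labels
  stopifnot(length(labels) == dim(aligned)[3])
  states <- sort(unique(labels))
  if (length(states) != 2)
    stop("scatter_matrices expects exactly two states in `labels`", call. = FALSE)
  X <- flatten_traj(aligned)
  m <- colMeans(X)
  S_w <- matrix(0, ncol(X), ncol(X))
  S_b <- matrix(0, ncol(X), ncol(X))
  cluster_means <- list()
  n_i <- integer(0)
  for (s in states) {
    Xi <- X[labels == s, , drop = FALSE]
    mi <- colMeans(Xi)
    Xc <- sweep(Xi, 2, mi)
    S_w <- S_w + crossprod(Xc)
    d <- mi - m
    S_b <- S_b + (if (population_weighted) nrow(Xi) else 1) * tcrossprod(d)
    cluster_means[[as.character(s)]] <- matrix(mi, ncol = 3)
    n_i <- c(n_i, nrow(Xi))
  }
  structure(list(S_w = S_w, S_b = S_b, cluster_means = cluster_means,
                 global_mean = matrix(m, ncol = 3), n = n_i, states = states),
            class = "scatter_pair")
}

#' Discriminant direction from a scatter pair
#'
#' Maximizes the LDA trace-ratio objective
#' \eqn{\mathrm{tr}[(G^T S_w G)^{-1} (G^T S_b G)]} for a single direction.
#' Aligned positional data always give a singular \eqn{S_w} (centering and
#' rotation removal constrain the data to a subspace), so the classical
#' eigenproblem is unusable; instead the generalized-SVD formulation is used:
#' an SVD of the stacked factor matrix \eqn{[H_b^T; H_w^T]} with rank
#' truncation at `tau` times the top singular value, followed by an SVD of
#' the leading block, yields the discriminant even when \eqn{S_w} is
#' singular.  For nonsingular \eqn{S_w} the result is parallel to
#' \eqn{S_w^{-1} (\mu_1 - \mu_2)}.
#'
#' @param scatter A [scatter_matrices()] result, or a list with data factors
#'   (`H_b`, `H_w`).
#' @param tau Relative singular-value cutoff.
#' @return Unit-norm numeric vector of length 3N.
#' @export
lda_direction <- function(scatter, tau = 1e-10) {
  stopifnot(inherits(scatter, "scatter_pair"))
  if (is.null(attr(scatter, "H_w"))) {
    # factor S_w, S_b through eigendecompositions (PSD square roots)
    H_w <- psd_factor(scatter$S_w)
    H_b <- psd_factor(scatter$S_b)
  } else {
    H_w <- attr(scatter, "H_w")
    H_b <- attr(scatter, "H_b")
  }
  if (max(abs(scatter$S_b)) < 1e-12)
    stop("degenerate separation: the two cluster means coincide", call. = FALSE)
  K <- cbind(H_b, H_w)               # 3N x (k + n)
  sv <- svd(t(K))                    # (k+n) x 3N
  t_rank <- sum(sv$d > tau * sv$d[1])
  P1 <- sv$u[seq_len(ncol(H_b)), seq_len(t_rank), drop = FALSE]
  sw <- svd(P1)
  G <- sv$v[, seq_len(t_rank), drop = FALSE] %*%
    (diag(1 / sv$d[seq_len(t_rank)], t_rank) %*% sw$v)
  v <- G[, 1]
  v / sqrt(sum(v^2))
}

psd_factor <- function(S) {
  e <- eigen(0.5 * (S + t(S)), symmetric = TRUE)
  keep <- e$values > max(e$values, 0) * 1e-12
  if (!any(keep)) return(matrix(0, nrow(S), 1))
  e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]), sum(keep))
}

#' Train a one-dimensional position-LDA coordinate between two states
#'
#' Composes [global_align()], [scatter_matrices()] and [lda_direction()]:
#' the pooled two-state trajectory is iteratively aligned to its global mean
#' and covariance, scatter matrices are built from the aligned positions, and
#' the discriminant direction is extracted by the singular-value route.  The
#' coefficient vector is unit-norm (so the coordinate \eqn{l} carries
#' Angstrom units of projected displacement) and its sign is fixed so that
#' frames of `state_a` project to negative values.  By construction
#' \eqn{l(\mu) = 0} at the global reference mean.
#'
#' @param traj Trajectory containing both states.
#' @param labels Per-frame labels ([assign_states()] result or a vector).
#' @param state_a,state_b The two state labels; `state_a` maps to negative l.
#' @param tol,max_iter Alignment controls, see [iterative_mean_cov()].
#' @param tau Rank-truncation cutoff for the discriminant SVD.
#' @return An object of class `poslda_model`: list with `v` (length 3N,
#'   unit norm), `ref` (global [shape_ref()]), `sign`, `states`, `meta`.
#' @examples
#' set.seed(1)
#' spec_a <- gaussian_state_spec(matrix(rnorm(15), 5, 3), diag(0.05, 5), 50, seed = 1)
#' spec_b <- gaussian_state_spec(spec_a$mean + 0.8, diag(0.05, 5), 50, seed = 2)
#' tr <- bind_traj(sample_gaussian_state(spec_a), sample_gaussian_state(spec_b))
#' model <- train_poslda(tr, rep(1:2, each = 50), 1, 2)
#' compute_cv(model$ref$mean, model)  # 0 at the reference mean
#' @export
train_poslda <- function(traj, labels, state_a, state_b, tol = 1e-8,
                         max_iter = 200, tau = 1e-10) {
  if (inherits(labels, "state_assignment")) labels <- labels$labels
  ga <- global_align(traj, labels, c(state_a, state_b), tol = tol,
                     max_iter = max_iter)
  n_a <- sum(ga$labels == state_a)
  n_b <- sum(ga$labels == state_b)
  if (n_a < 2 || n_b < 2)
    stop("both states need at least 2 frames", call. = FALSE)
  sc <- scatter_matrices(ga$aligned, ga$labels)
  v <- lda_direction(sc, tau = tau)
  l_a <- mean(cpp_cv_many(unclass(subset_frames(ga$aligned, ga$labels == state_a)),
                          ga$ref$mean, ga$ref$precision, v))
  sign_flag <- if (l_a > 0) -1 else 1
  v <- sign_flag * v
  structure(
    list(v = v, ref = ga$ref, sign = sign_flag,
         states = c(a = state_a, b = state_b),
         meta = list(n_a = n_a, n_b = n_b, n_particles = nrow(ga$ref$mean),
                     rank = ga$ref$rank, tol = tol, tau = tau)),
    class = "poslda_model"
  )
}

#' @export
print.poslda_model <- function(x, ...) {
  cat(sprintf("<position-LDA model: %d particles, states %s -> negative / %s -> positive>\n",
              x$meta$n_particles, x$states["a"], x$states["b"]))
  invisible(x)
}

check_model <- function(model) {
  if (!inherits(model, "poslda_model")) stop("expected a poslda_model", call. = FALSE)
  model
}

#' Project a trajectory onto a trained LDA coordinate
#'
#' Each frame is centered, rotated onto the model's global reference with the
#' Mahalanobis-optimal rotation, and projected:
#' \eqn{l = v \cdot (x_{aligned} - \mu)}.  Rigid motions of the input leave
#' \eqn{l} unchanged.
#'
#' @param traj Trajectory (or single frame) to project.
#' @param model A [train_poslda()] model.
#' @return A tibble with columns `frame` and `l` (Angstrom).
#' @export
project_cv <- function(traj, model) {
  model <- check_model(model)
  traj <- as_traj(traj)
  if (dim(traj)[1] != model$meta$n_particles)
    stop("trajectory and model have different particle counts", call. = FALSE)
  l <- cpp_cv_many(unclass(traj), model$ref$mean, model$ref$precision, model$v)
  tibble::tibble(frame = seq_along(l), l = as.numeric(l))
}

#' @export
predict.poslda_model <- function(object, newdata, ...) {
  project_cv(newdata, object)$l
}

#' @describeIn train_poslda Per-particle coefficient triples of the trained
#'   direction (the data behind a porcupine plot).
#' @param x A `poslda_model`.
#' @param ... Unused.
#' @export
tidy.poslda_model <- function(x, ...) {
  V <- matrix(x$v, ncol = 3)
  tibble::tibble(particle = seq_len(nrow(V)), vx = V[, 1], vy = V[, 2],
                 vz = V[, 3], magnitude = sqrt(rowSums(V^2)))
}

#' @describeIn train_poslda One-row model summary.
#' @export
glance.poslda_model <- function(x, ...) {
  tibble::tibble(n_particles = x$meta$n_particles, n_a = x$meta$n_a,
                 n_b = x$meta$n_b, cov_rank = x$meta$rank,
                 state_a = unname(x$states["a"]), state_b = unname(x$states["b"]),
                 norm_v = sqrt(sum(x$v^2)))
}

#' Concatenate trajectories
#' @param ... Trajectories (or coercible objects) with equal particle counts.
#' @return A single `ldacv_traj`.
#' @export
bind_traj <- function(...) {
  parts <- lapply(list(...), as_traj)
  N <- unique(vapply(parts, function(p) dim(p)[1], integer(1)))
  if (length(N) != 1) stop("particle counts differ", call. = FALSE)
  as_traj(array(unlist(parts), dim = c(N, 3, sum(vapply(parts, n_frames, integer(1))))),
          ids = attr(parts[[1]], "ids"))
}
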