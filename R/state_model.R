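#' A set of discrete conformational states
#'
#' Holds the shape references \eqn{\{\mu_j, \Sigma_j\}} of `K` states together
#' with their mixture weights \eqn{\phi_j} (normalized population fractions).
#'
#' @param refs List of [shape_ref()] objects sharing the same particle count.
#' @param weights Optional per-state weights; defaults to equal weights.
#'   Normalized to sum to one.
#' @return An object of class `state_set`.
#' @export
state_set <- function(refs, weights = NULL) {
  stopifnot(is.list(refs), length(refs) >= 1)
  lapply(refs, check_ref)
  Ns <- vapply(refs, function(r) nrow(r$mean), integer(1))
  if (length(unique(Ns)) != 1)
    stop("all state references must share the particle count", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(refs))
  stopifnot(length(weights) == length(refs), all(weights > 0))
  weights <- weights / sum(weights)
  for (j in seq_along(refs)) refs[[j]]$weight <- weights[j]
  structure(list(refs = refs, weights = weights), class = "state_set")
}

#' @export
print.state_set <- function(x, ...) {
  cat(sprintf("<state set: %d states, %d particles, weights %s>\n",
              length(x$refs), nrow(x$refs[[1]]$mean),
              paste(sprintf("%.3f", x$weights), collapse = "/")))
  invisible(x)
}

#' Assign frames to states by nearest Mahalanobis distance
#'
#' Each frame is aligned independently to every state reference, and its
#' label is the state with the smallest squared Mahalanobis distance (ties
#' broken by the lowest state index).  The assignment is invariant to rigid
#' motion of any input frame.
#'
#' @param traj Trajectory to assign.
#' @param states A [state_set()].
#' @return An object of class `state_assignment`: a list with `labels`
#'   (per-frame state index, 1-based) and `distances` (frames x states matrix
#'   of squared Mahalanobis distances).  `as_tibble()` gives a long view.
#' @export
assign_states <- function(traj, states) {
  traj <- as_traj(traj)
  stopifnot(inherits(states, "state_set"))
  if (dim(traj)[1] != nrow(states$refs[[1]]$mean))
    stop("trajectory and states have different particle counts", call. = FALSE)
  D <- vapply(states$refs, function(r)
    cpp_mahal_traj(unclass(traj), r$mean, r$precision),
    numeric(dim(traj)[3]))
  D <- matrix(D, nrow = dim(traj)[3])
  labels <- apply(D, 1, which.min)  # which.min breaks ties at lowest index
  structure(list(labels = as.integer(labels), distances = D),
            class = "state_assignment")
}

#' @export
print.state_assignment <- function(x, ...) {
  tb <- table(x$labels)
  cat(sprintf("<state assignment: %d frames; populations %s>\n",
              length(x$labels),
              paste(sprintf("%s:%d", names(tb), tb), collapse = " ")))
  invisible(x)
}

#' @export
as_tibble.state_assignment <- function(x, ...) {
  tibble::tibble(frame = seq_along(x$labels), state = x$labels,
                 dist_sq = x$distances[cbind(seq_along(x$labels), x$labels)])
}

#' Hard-assignment fitting of K states
#'
#' A deliberately simple alternative to full expectation-maximization over a
#' Gaussian mixture in size-and-shape space: alternate per-state
#' [iterative_mean_cov()] on the currently assigned frames and
#' [assign_states()] over the pooled trajectory, until the labels stop
#' changing.  State weights are population fractions.
#'
#' @param traj Trajectory to cluster.
#' @param K Number of states.
#' @param init_labels Initial per-frame labels (1..K); every state must be
#'   represented.
#' @param tol Alignment tolerance passed to [iterative_mean_cov()].
#' @param max_iter Maximum label-update sweeps.
#' @return A [state_set()] with attributes `labels` (final assignment) and
#'   `sweeps`.
#' @export
fit_hard_states <- function(traj, K, init_labels, tol = 1e-6, max_iter = 50) {
  traj <- as_traj(traj)
  n <- dim(traj)[3]
  init_labels <- as.integer(init_labels)
  stopifnot(length(init_labels) == n)
  if (!setequal(unique(init_labels), seq_len(K)))
    stop("init_labels must cover all K states", call. = FALSE)
  labels <- init_labels
  states <- NULL
  for (sweep in seq_len(max_iter)) {
    refs <- vector("list", K)
    for (j in seq_len(K)) {
      idx <- which(labels == j)
      if (length(idx) < 2)
        stop(sprintf("state %d became empty during fitting", j), call. = FALSE)
      refs[[j]] <- iterative_mean_cov(subset_frames(traj, idx), tol = tol)
      attr(refs[[j]], "aligned") <- NULL
    }
    states <- state_set(refs, weights = tabulate(labels, K) / n)
    new_labels <- assign_states(traj, states)$labels
    if (all(new_labels == labels)) {
      attr(states, "labels") <- labels
      attr(states, "sweeps") <- sweep
      return(states)
    }
    labels <- new_labels
    if (!all(seq_len(K) %in% labels))
      stop(sprintf("state %d became empty during fitting",
                   setdiff(seq_len(K), unique(labels))[1]), call. = FALSE)
  }
  warning("hard-state fitting did not converge; returning last iterate")
  attr(states, "labels") <- labels
  attr(states, "sweeps") <- max_iter
  states
}
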