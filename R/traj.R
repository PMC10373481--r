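#' Trajectory containers
#'
#' A trajectory is an ordered set of frames with a fixed particle count; a
#' frame is an `N x 3` matrix of coordinates in Angstrom.  Internally a
#' trajectory is stored as an `N x 3 x n_frames` array of class `ldacv_traj`
#' with an optional `ids` attribute carrying ordered particle identifiers.
#'
#' @param x A single `N x 3` matrix, an `N x 3 x M` array, a list of `N x 3`
#'   matrices, or an existing `ldacv_traj`.
#' @param ids Optional ordered particle identifiers (length `N`).
#' @return An `ldacv_traj` array.
#' @examples
#' tr <- as_traj(matrix(rnorm(30), 10, 3))
#' n_frames(tr)
#' @export
as_traj <- function(x, ids = NULL) {
  if (inherits(x, "ldacv_traj")) {
    if (!is.null(ids)) attr(x, "ids") <- ids
    return(x)
  }
  if (is.list(x)) {
    stopifnot(length(x) >= 1)
    N <- nrow(x[[1]])
    if (!all(vapply(x, function(f) identical(dim(f), c(N, 3L)), logical(1))))
      stop("inconsistent particle count across frames", call. = FALSE)
    a <- array(unlist(x), dim = c(N, 3, length(x)))
  } else if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    a <- array(x, dim = c(nrow(x), 3, 1))
  } else if (is.array(x) && length(dim(x)) == 3) {
    stopifnot(dim(x)[2] == 3)
    a <- x
  } else {
    stop("cannot interpret input as a trajectory", call. = FALSE)
  }
  if (!all(is.finite(a))) stop("non-finite coordinates", call. = FALSE)
  structure(a, class = "ldacv_traj", ids = ids)
}

#' @rdname as_traj
#' @export
n_frames <- function(x) dim(as_traj(x))[3]

#' @rdname as_traj
#' @export
n_particles <- function(x) dim(as_traj(x))[1]

#' Extract one frame from a trajectory
#' @param traj An `ldacv_traj` (or coercible object).
#' @param i Frame index.
#' @return An `N x 3` coordinate matrix.
#' @export
get_frame <- function(traj, i) {
  traj <- as_traj(traj)
  traj[, , i, drop = TRUE]
}

#' Subset frames of a trajectory
#' @inheritParams get_frame
#' @param idx Frame indices to keep.
#' @export
subset_frames <- function(traj, idx) {
  traj <- as_traj(traj)
  as_traj(traj[, , idx, drop = FALSE], ids = attr(traj, "ids"))
}

#' @export
print.ldacv_traj <- function(x, ...) {
  cat(sprintf("<trajectory: %d frames x %d particles>\n", dim(x)[3], dim(x)[1]))
  invisible(x)
}

#' Long-format view of a trajectory
#'
#' @param x An `ldacv_traj`.
#' @param ... Unused.
#' @return A tibble with columns `frame`, `particle`, `x`, `y`, `z`.
#' @export
as_tibble.ldacv_traj <- function(x, ...) {
  d <- dim(x)
  ids <- attr(x, "ids")
  if (is.null(ids)) ids <- seq_len(d[1])
  tibble::tibble(
    frame = rep(seq_len(d[3]), each = d[1]),
    particle = rep(ids, d[3]),
    x = c(x[, 1, ]), y = c(x[, 2, ]), z = c(x[, 3, ])
  )
}

#' Build a trajectory from a long-format table
#'
#' Inverse of [as_tibble.ldacv_traj()]: takes a data frame with columns
#' `frame`, `particle`, `x`, `y`, `z` and returns an `ldacv_traj`.
#'
#' @param data A data frame in long format.
#' @return An `ldacv_traj`.
#' @export
traj_from_tibble <- function(data) {
  stopifnot(all(c("frame", "particle", "x", "y", "z") %in% names(data)))
  data <- data[order(data$frame), , drop = FALSE]
  frames <- split(data, data$frame)
  ids <- frames[[1]]$particle
  as_traj(lapply(frames, function(d) cbind(d$x, d$y, d$z)), ids = ids)
}

check_frame <- function(frame) {
  if (inherits(frame, "ldacv_traj")) {
    stopifnot(dim(frame)[3] == 1)
    frame <- frame[, , 1, drop = TRUE]
  }
  if (!is.matrix(frame) || ncol(frame) != 3)
    stop("a frame must be an N x 3 matrix", call. = FALSE)
  if (nrow(frame) < 3) stop("a frame needs at least 3 particles", call. = FALSE)
  if (!all(is.finite(frame))) stop("non-finite coordinates", call. = FALSE)
  frame
}

#' Remove the centroid of a frame
#'
#' Translates a configuration so that its geometric mean sits at the origin,
#' the first step of mapping a configuration into size-and-shape space.
#'
#' @param frame An `N x 3` coordinate matrix (Angstrom).
#' @return The centered `N x 3` matrix; the input is not modified.
#' @examples
#' f <- matrix(rnorm(30), 10, 3) + 5
#' colMeans(center_frame(f))
#' @export
center_frame <- function(frame) {
  frame <- check_frame(frame)
  sweep(frame, 2, colMeans(frame))
}
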