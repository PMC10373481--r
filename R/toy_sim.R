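#' Specification of a Gaussian shape state
#'
#' Describes the generative model the alignment machinery assumes: frames
#' drawn from a multivariate Gaussian in particle positions with mean `mean`
#' and Kronecker covariance `cov` \eqn{\otimes I_3} (the same particle
#' covariance acting independently on x, y, z), each frame then given a
#' random rigid translation and rotation when `pose` is on.
#'
#' @param mean `N x 3` mean structure (Angstrom).
#' @param cov `N x N` positive semi-definite particle covariance
#'   (Angstrom^2).
#' @param n_frames Number of frames to draw.
#' @param pose If `TRUE`, apply an independent uniform random rotation and a
#'   uniform translation in `[-box, box]^3` to every frame.
#' @param box Half-width of the translation box (Angstrom).
#' @param seed Integer seed; fixes the whole sample.
#' @return A list of class `gaussian_state_spec`.
#' @export
gaussian_state_spec <- function(mean, cov, n_frames, pose = TRUE, box = 10,
                                seed = 1) {
  mean <- check_frame(mean)
  stopifnot(is.matrix(cov), nrow(cov) == nrow(mean), ncol(cov) == nrow(mean))
  ev <- eigen(0.5 * (cov + t(cov)), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("covariance is not positive semi-definite", call. = FALSE)
  structure(list(mean = mean, cov = 0.5 * (cov + t(cov)), n_frames = n_frames,
                 pose = pose, box = box, seed = seed),
            class = "gaussian_state_spec")
}

random_rotation <- function() {
  # uniform over SO(3) via a normalized Gaussian quaternion
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Draw posed frames from a Gaussian shape state
#'
#' @param spec A [gaussian_state_spec()].
#' @return An `ldacv_traj` with `spec$n_frames` frames.  The draw is fully
#'   determined by `spec$seed`.
#' @export
sample_gaussian_state <- function(spec) {
  stopifnot(inherits(spec, "gaussian_state_spec"))
  set.seed(spec$seed)
  N <- nrow(spec$mean)
  e <- eigen(spec$cov, symmetric = TRUE)
  sqrt_cov <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), N) %*% t(e$vectors)
  frames <- array(0, dim = c(N, 3, spec$n_frames))
  for (f in seq_len(spec$n_frames)) {
    X <- spec$mean + sqrt_cov %*% matrix(rnorm(3 * N), N, 3)
    if (spec$pose) {
      X <- X %*% random_rotation()
      X <- sweep(X, 2, runif(3, -spec$box, spec$box), `+`)
    }
    frames[, , f] <- X
  }
  as_traj(frames)
}

# Sequential (NeRF) placement: position atom D given A-B-C with bond |CD|,
# angle B-C-D and torsion A-B-C-D.
place_atom <- function(A, B, C, bond, angle, torsion) {
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(angle), bond * cos(torsion) * sin(angle),
          bond * sin(torsion) * sin(angle))
  C + cbind(bc, m, n) %*% d2
}

#' Build a chain of particles from internal coordinates
#'
#' Places particles sequentially from bond lengths, bond angles and torsion
#' angles (NeRF construction).  Entry `i` of `bonds`/`angles`/`torsions`
#' positions particle `i + 3` relative to the three preceding ones.
#'
#' @param bonds Bond lengths (length `N - 1`, Angstrom).
#' @param angles Bond angles (length `N - 2`, radians).
#' @param torsions Torsion angles (length `N - 3`, radians).
#' @return `N x 3` coordinate matrix.
#' @export
build_chain <- function(bonds, angles, torsions) {
  N <- length(bonds) + 1
  stopifnot(length(angles) == N - 2, length(torsions) == N - 3)
  X <- matrix(0, N, 3)
  X[2, ] <- c(bonds[1], 0, 0)
  X[3, ] <- X[2, ] + bonds[2] * c(-cos(angles[1]), sin(angles[1]), 0)
  for (i in seq_len(N - 3)) {
    X[i + 3, ] <- place_atom(X[i, ], X[i + 1, ], X[i + 2, ], bonds[i + 2],
                             angles[i + 1], torsions[i])
  }
  X
}

#' Ideal polypeptide backbone from phi/psi angles
#'
#' Builds an N-CA-C backbone with standard bond lengths and angles and the
#' given repeating torsions, for use with [zeta_prime()].  The phi dihedral
#' of residue `n` is C(n-1)-N(n)-CA(n)-C(n).
#'
#' @param n_res Number of residues.
#' @param phi,psi,omega Backbone torsions in radians (defaults: ideal
#'   right-handed 3-10 helix, phi = -57 degrees).
#' @return `(3 n_res) x 3` coordinate matrix with attribute `phi_quads`, the
#'   atom quadruples of the phi dihedrals of residues `2..n_res`.
#' @export
build_helix_backbone <- function(n_res, phi = -57 * pi / 180,
                                 psi = -30 * pi / 180, omega = pi) {
  b <- rep(c(1.458, 1.525, 1.329), n_res)[seq_len(3 * n_res - 1)]
  a <- rep(c(111, 116.2, 121.7) * pi / 180, n_res)[seq_len(3 * n_res - 2)]
  t <- rep(c(psi, omega, phi), n_res)[seq_len(3 * n_res - 3)]
  X <- build_chain(b, a, t)
  quads <- t(vapply(2:n_res, function(n) {
    i <- 3L * (n - 1L)  # C of residue n-1
    c(i, i + 1L, i + 2L, i + 3L)
  }, integer(4)))
  attr(X, "phi_quads") <- quads
  X
}

#' Five-particle chiral toy system
#'
#' A minimal stand-in for a helix-inversion problem: a chain of five
#' particles held by harmonic bonds and angles, with a quartic double well on
#' the signed dihedral of particles 1-2-3-4 creating two mirror-image minima
#' (the potential is exactly mirror-symmetric, so the two basins have equal
#' free energy by construction), and a weak harmonic term keeping the second
#' dihedral near planarity.  The default barrier is `6 kB * 300` kcal/mol.
#'
#' @param barrier Double-well barrier height (kcal/mol).
#' @param phi0 Location of the dihedral minima (radians).
#' @param temperature Default thermostat temperature (K).
#' @param friction Langevin friction (1/ps).
#' @param dt Integration time step (ps).
#' @param mass Particle mass (amu).
#' @return A list of class `toy_system` with the potential terms, an
#'   energy-minimized starting structure `x0` (right-handed basin), and the
#'   dihedral quadruple `handed_quad` defining the handedness order
#'   parameter.
#' @export
toy_chiral_system <- function(barrier = 6 * kB * 300, phi0 = 1.2,
                              temperature = 300, friction = 1, dt = 0.002,
                              mass = 12) {
  bonds <- cbind(i = 1:4, j = 2:5, r0 = 1.5, k = 100)
  angles <- cbind(i = 1:3, j = 2:4, k = 3:5, th0 = 1.9, kth = 30)
  torsions <- rbind(c(1, 2, 3, 4, 1, barrier, phi0),
                    c(2, 3, 4, 5, 2, 3, 0))
  x0 <- build_chain(rep(1.5, 4), rep(1.9, 3), c(phi0, 0))
  x0 <- cpp_minimize_toy(x0, bonds, angles, torsions, 2000, 1e-3)
  sys <- structure(
    list(n_particles = 5L, bonds = bonds, angles = angles, torsions = torsions,
         masses = rep(mass, 5), temperature = temperature, friction = friction,
         dt = dt, barrier = barrier, phi0 = phi0, x0 = x0,
         handed_quad = c(1L, 2L, 3L, 4L)),
    class = "toy_system")
  sys
}

#' @export
print.toy_system <- function(x, ...) {
  cat(sprintf("<toy system: %d particles, dihedral barrier %.2f kcal/mol at phi0 = %.2f rad>\n",
              x$n_particles, x$barrier, x$phi0))
  invisible(x)
}

#' Potential energy and forces of a toy system
#' @param frame `N x 3` coordinate matrix.
#' @param system A [toy_chiral_system()].
#' @return List with `energy` (kcal/mol) and `force` (`N x 3`).
#' @export
toy_energy <- function(frame, system) {
  cpp_toy_energy_force(check_frame(frame), system$bonds, system$angles,
                       system$torsions)
}

#' Energy-minimize a toy-system configuration
#' @inheritParams toy_energy
#' @param n_iter Maximum steepest-descent iterations.
#' @return The relaxed `N x 3` matrix.
#' @export
minimize_toy <- function(frame, system, n_iter = 2000) {
  cpp_minimize_toy(check_frame(frame), system$bonds, system$angles,
                   system$torsions, n_iter, 1e-3)
}

#' Handedness order parameter of a toy frame
#'
#' The signed dihedral angle (radians) summed over the system's defining
#' quadruple(s); it changes sign exactly under mirror reflection of the
#' frame, and the two minimized basins of the chiral toy have opposite
#' signs.
#'
#' @inheritParams toy_energy
#' @return Scalar, radians.
#' @export
handedness <- function(frame, system) {
  frame <- check_frame(frame)
  q <- matrix(system$handed_quad, ncol = 4)
  sum(apply(q, 1, function(r) cpp_dihedral(frame, r[1], r[2], r[3], r[4])))
}

#' Run Langevin dynamics on a toy system
#'
#' BAOAB-split Langevin integration (velocity Verlet in the zero-friction
#' limit), optionally biased along a collective variable by well-tempered
#' metadynamics or OPES, with optional quadratic walls.  Bias forces
#' \eqn{-dV/dl \, \nabla l} are applied every step; deposition happens every
#' `pace` steps.  Fully reproducible from `seed`.
#'
#' @param system A [toy_chiral_system()].
#' @param n_steps Number of integration steps.
#' @param seed Integer RNG seed.
#' @param temperature Thermostat temperature (K); defaults to the system's.
#' @param x0 Starting configuration; defaults to the system's minimized
#'   structure.
#' @param bias `NULL` for unbiased dynamics, or a list with `method`
#'   (`"wtmetad"` or `"opes"`), `cv` (a [train_poslda()] model, or the string
#'   `"dihedral"` to bias the handedness dihedral directly), `pace`, grid
#'   controls `qmin`, `qmax`, `ngrid`, and the method parameters: `height`,
#'   `sigma`, `gamma` for WT-MetaD; `sigma`, `gamma`, `deltaE` for OPES.
#' @param walls Optional list `(lower, upper, kappa)` for quadratic walls on
#'   the CV.
#' @param stride Record every `stride`-th step.
#' @param fd_step Finite-difference step for the CV gradient (Angstrom).
#' @return A list of class `langevin_run`: `traj` (recorded frames),
#'   `colvar` (tibble: `time`, `cv`, `bias`, `wall`, `energy`,
#'   `handedness`), `hills` or `kernels` tibble when biased, `grid` (tibble
#'   `q`, `bias` of the final bias), `max_force`, `crashed`, `crash_step`.
#' @export
run_langevin <- function(system, n_steps, seed = 1,
                         temperature = system$temperature, x0 = system$x0,
                         bias = NULL, walls = NULL, stride = 10,
                         fd_step = 1e-4) {
  stopifnot(inherits(system, "toy_system"), n_steps >= stride)
  bias_type <- 0L
  bias_params <- list()
  cv_type <- 0L
  cv_params <- list(quad = as.integer(system$handed_quad))
  if (!is.null(bias)) {
    bias_type <- switch(bias$method, wtmetad = 1L, opes = 2L,
                        stop("unknown bias method", call. = FALSE))
    need <- c("pace", "qmin", "qmax", "ngrid", "sigma", "gamma",
              if (bias_type == 1L) "height" else "deltaE")
    missing <- setdiff(need, names(bias))
    if (length(missing) > 0)
      stop("missing bias parameters: ", paste(missing, collapse = ", "),
           call. = FALSE)
    if (bias$gamma <= 1) stop("gamma must be > 1", call. = FALSE)
    bias_params <- bias[need]
    bias_params$pace <- as.integer(bias_params$pace)
    bias_params$ngrid <- as.integer(bias_params$ngrid)
    if (!is.null(bias$cv) && inherits(bias$cv, "poslda_model")) {
      cv_type <- 1L
      cv_params <- list(mean = bias$cv$ref$mean,
                        precision = bias$cv$ref$precision, v = bias$cv$v,
                        fd_step = fd_step)
    }
  }
  use_walls <- !is.null(walls)
  if (use_walls) stopifnot(walls$lower < walls$upper, walls$kappa > 0)
  res <- cpp_run_toy(x0, system$bonds, system$angles, system$torsions,
                     system$masses, system$dt, system$friction, temperature,
                     as.integer(n_steps), as.integer(seed), as.integer(stride),
                     bias_type, bias_params, cv_type, cv_params, use_walls,
                     if (use_walls) walls$lower else 0,
                     if (use_walls) walls$upper else 0,
                     if (use_walls) walls$kappa else 0,
                     as.integer(system$handed_quad))
  if (res$crashed)
    stop(sprintf("non-finite force at step %d (integration crash); last frame dumped in result",
                 res$crash_step), call. = FALSE)
  out <- list(
    traj = as_traj(res$frames),
    colvar = tibble::tibble(time = as.numeric(res$time),
                            cv = as.numeric(res$cv),
                            bias = as.numeric(res$bias),
                            wall = as.numeric(res$wall),
                            energy = as.numeric(res$energy),
                            handedness = as.numeric(res$handedness)),
    max_force = res$max_force, crashed = res$crashed,
    crash_step = res$crash_step, temperature = temperature, seed = seed,
    bias = bias
  )
  if (bias_type == 1L) {
    out$hills <- tibble::tibble(center = as.numeric(res$hill_centers),
                                height = as.numeric(res$hill_heights),
                                width = bias$sigma)
    out$grid <- tibble::tibble(q = as.numeric(res$grid_q),
                               bias = as.numeric(res$grid_bias))
  } else if (bias_type == 2L) {
    out$kernels <- tibble::tibble(center = as.numeric(res$kernel_centers),
                                  weight = as.numeric(res$kernel_weights),
                                  width = bias$sigma)
    out$grid <- tibble::tibble(q = as.numeric(res$grid_q),
                               bias = as.numeric(res$grid_bias))
  }
  class(out) <- "langevin_run"
  out
}

#' @export
print.langevin_run <- function(x, ...) {
  cat(sprintf("<langevin run: %d recorded frames at T = %g K%s>\n",
              n_frames(x$traj), x$temperature,
              if (!is.null(x$bias)) paste0(", ", x$bias$method, " bias") else ""))
  invisible(x)
}

#' Run biased Langevin dynamics on an analytic 1D double well
#'
#' A single coordinate in \eqn{U(x) = a ((x/x_0)^2 - 1)^2} with the bias
#' acting directly on `x`; used to validate the bias machinery against an
#' exactly known free energy surface.
#'
#' @param a Barrier height (kcal/mol).
#' @param x0 Well position (Angstrom); minima at `-x0` and `x0`.  Setting
#'   `x0 = 0` selects the harmonic limit \eqn{U = a x^2} (spring constant
#'   `2a`), handy for equipartition checks.
#' @param n_steps,seed,temperature,stride As in [run_langevin()].
#' @param mass,friction,dt Particle mass (amu), friction (1/ps), step (ps).
#' @param x_init Starting position.
#' @param bias As in [run_langevin()] (no `cv` entry; the coordinate itself
#'   is biased).
#' @return List with `colvar` (tibble `time`, `x`, `bias`), `grid`, `hills`
#'   or `kernels`.
#' @export
run_double_well <- function(a, x0 = 1, n_steps = 1e5, seed = 1,
                            temperature = 300, mass = 12, friction = 5,
                            dt = 0.002, x_init = -x0, bias = NULL,
                            stride = 10) {
  bias_type <- 0L
  bias_params <- list()
  if (!is.null(bias)) {
    bias_type <- switch(bias$method, wtmetad = 1L, opes = 2L,
                        stop("unknown bias method", call. = FALSE))
    need <- c("pace", "qmin", "qmax", "ngrid", "sigma", "gamma",
              if (bias_type == 1L) "height" else "deltaE")
    bias_params <- bias[need]
    bias_params$pace <- as.integer(bias_params$pace)
    bias_params$ngrid <- as.integer(bias_params$ngrid)
  }
  res <- cpp_run_dw1d(x_init, a, x0, mass, dt, friction, temperature,
                      as.integer(n_steps), as.integer(seed),
                      as.integer(stride), bias_type, bias_params)
  out <- list(colvar = tibble::tibble(time = as.numeric(res$time),
                                      x = as.numeric(res$x),
                                      bias = as.numeric(res$bias)))
  if (bias_type == 1L)
    out$hills <- tibble::tibble(center = as.numeric(res$hill_centers),
                                height = as.numeric(res$hill_heights),
                                width = bias$sigma)
  if (bias_type == 2L)
    out$kernels <- tibble::tibble(center = as.numeric(res$kernel_centers),
                                  weight = as.numeric(res$kernel_weights),
                                  width = bias$sigma)
  if (bias_type != 0L)
    out$grid <- tibble::tibble(q = as.numeric(res$grid_q),
                               bias = as.numeric(res$grid_bias))
  out
}

#' Count transitions of a signed order parameter
#'
#' Counts crossings between the two basins with hysteresis: a transition is
#' recorded each time the series, having been beyond one threshold, reaches
#' beyond the opposite one.
#'
#' @param x Numeric series (e.g. handedness).
#' @param threshold Hysteresis half-width; basins are `x < -threshold` and
#'   `x > threshold`.
#' @return Integer transition count.
#' @export
count_transitions <- function(x, threshold = 0.6) {
  state <- 0L
  n <- 0L
  for (v in x) {
    s <- if (v > threshold) 1L else if (v < -threshold) -1L else 0L
    if (s != 0L) {
      if (state != 0L && s != state) n <- n + 1L
      state <- s
    }
  }
  n
}
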