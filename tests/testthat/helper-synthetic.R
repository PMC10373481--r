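# Shared builders for synthetic fixtures; everything is generated in code.

# centered random mean structure with radius of gyration ~ 2*scale
random_mean <- function(N, scale = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- matrix(rnorm(N * 3), N, 3)
  sweep(mu, 2, colMeans(mu)) * scale
}

random_proper_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

apply_rigid <- function(frame, R = random_proper_rotation(),
                        shift = runif(3, -8, 8)) {
  sweep(frame %*% R, 2, shift, `+`)
}

# structured PSD particle covariance: diagonal floor + two soft modes
structured_cov <- function(N, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  u1 <- rnorm(N); u2 <- rnorm(N)
  0.02 * diag(N) + 0.3 * tcrossprod(u1) / N + 0.15 * tcrossprod(u2) / N
}

# two Gaussian states separated along a random direction; molecular regime:
# positional noise well below the structure size
two_state_data <- function(N = 10, n_per = 200, sep = 1.2, sig2 = 0.04,
                           scale = 3.5, seed = 1, pose = TRUE) {
  set.seed(seed)
  mu_a <- random_mean(N, scale)
  d <- rnorm(N * 3)
  d <- d / sqrt(sum(d^2))
  mu_b <- mu_a + sep * matrix(d, N, 3)
  traj <- bind_traj(
    sample_gaussian_state(gaussian_state_spec(mu_a, diag(sig2, N), n_per,
                                              pose = pose, seed = seed * 10 + 1)),
    sample_gaussian_state(gaussian_state_spec(mu_b, diag(sig2, N), n_per,
                                              pose = pose, seed = seed * 10 + 2)))
  list(traj = traj, labels = rep(1:2, each = n_per), mu_a = mu_a, mu_b = mu_b,
       d = d, sig2 = sig2)
}

# fake "aligned" trajectory holding an arbitrary n x 3N data matrix, for
# scatter/LDA oracle tests that need full-rank instances
traj_from_matrix <- function(X, N) {
  as_traj(array(t(X), dim = c(N, 3, nrow(X))))
}

# projector onto the centered subspace (ones vector removed)
centering_projector <- function(N) diag(N) - matrix(1 / N, N, N)
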