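test_that("center_frame removes any translation and leaves centered frames alone", {
  set.seed(1)
  f <- random_mean(10)
  expect_equal(center_frame(f), f, tolerance = 1e-12)
  shifted <- sweep(f, 2, c(5, -2, 1), `+`)
  expect_equal(center_frame(shifted), center_frame(f), tolerance = 1e-12)
  expect_lt(max(abs(colMeans(center_frame(matrix(rnorm(30), 10, 3))))), 1e-12)
  expect_error(center_frame(matrix(c(1, NA, rep(1, 28)), 10, 3)), "finite")
})

test_that("optimal rotation solves the precision-weighted Kabsch problem", {
  set.seed(2)
  N <- 8
  mu <- random_mean(N)
  ref_iso <- shape_ref(mu, diag(N))
  X <- mu + 0.1 * matrix(rnorm(N * 3), N, 3)
  posed <- apply_rigid(X)

  # identity covariance: agreement with an independent classical Kabsch SVD
  Xc <- center_frame(posed)
  H <- t(Xc) %*% mu
  sv <- svd(H)
  Rk <- sv$u %*% diag(c(1, 1, sign(det(sv$u %*% t(sv$v))))) %*% t(sv$v)
  g <- optimal_rotation(posed, ref_iso)
  expect_equal(g$rotation, Rk, tolerance = 1e-8)
  expect_equal(t(g$rotation) %*% g$rotation, diag(3), tolerance = 1e-10)
  expect_equal(det(g$rotation), 1, tolerance = 1e-10)

  # frame equal to the mean: exact identity rotation
  g0 <- optimal_rotation(mu, ref_iso)
  expect_equal(g0$rotation, diag(3), tolerance = 1e-8)

  # weighted case beats 100 random rotations
  S <- structured_cov(N, seed = 3)
  ref_w <- shape_ref(mu, S)
  A <- align_frame(posed, ref_w)
  d_opt <- mahalanobis_sq(A, ref_w)
  set.seed(4)
  for (i in 1:100) {
    Xr <- center_frame(posed) %*% random_proper_rotation()
    expect_lte(d_opt, mahalanobis_sq(Xr, ref_w) + 1e-10)
  }

  # degenerate collinear frame falls back to identity with a warning
  line <- cbind(1:5, 0, 0)
  expect_warning(gl <- optimal_rotation(line, shape_ref(random_mean(5), diag(5))),
                 "degenerate")
  expect_equal(gl$rotation, diag(3))

  expect_error(optimal_rotation(matrix(0, 4, 3), ref_iso), "particle counts")
})

test_that("alignment is idempotent and collapses whole equivalence classes", {
  set.seed(5)
  N <- 9
  mu <- random_mean(N)
  ref <- shape_ref(mu, structured_cov(N, seed = 6))
  X <- mu + 0.2 * matrix(rnorm(N * 3), N, 3)
  A <- align_frame(X, ref)
  expect_equal(align_frame(mu, ref), ref$mean, tolerance = 1e-8)
  expect_lt(max(abs(align_frame(A, ref) - A)), 1e-8)
  for (i in 1:20) {
    expect_lt(max(abs(align_frame(apply_rigid(X), ref) - A)), 1e-8)
  }
})

test_that("squared Mahalanobis distance matches its chi-square expectation", {
  set.seed(7)
  N <- 6
  mu <- random_mean(N)
  S <- structured_cov(N, seed = 8)
  P <- centering_projector(N)
  ref <- shape_ref(mu, P %*% S %*% P)

  expect_equal(mahalanobis_sq(ref$mean, ref), 0)
  # identity covariance reduces to the plain squared Euclidean distance
  ref_iso <- shape_ref(mu, diag(N))
  X <- center_frame(mu + 0.1 * matrix(rnorm(N * 3), N, 3))
  expect_equal(mahalanobis_sq(X, ref_iso), sum((X - ref_iso$mean)^2),
               tolerance = 1e-10)
  expect_error(mahalanobis_sq(sweep(X, 2, c(1, 0, 0), `+`), ref_iso),
               "not centered")

  # Monte-Carlo: mean over draws ~ 3 * rank (per-Cartesian-dimension
  # chi-square); frames drawn in the reference pose and measured directly
  spec <- gaussian_state_spec(mu, ref$cov, 10000, pose = FALSE, seed = 9)
  tr <- sample_gaussian_state(spec)
  d <- vapply(seq_len(n_frames(tr)), function(i)
    mahalanobis_sq(center_frame(get_frame(tr, i)), ref), numeric(1))
  expect_equal(mean(d), 3 * ref$rank, tolerance = 0.05)
})

test_that("iterative mean/covariance estimation recovers the generator", {
  set.seed(10)
  N <- 10
  mu <- random_mean(N, scale = 3.5)
  S <- structured_cov(N, seed = 11)
  spec <- gaussian_state_spec(mu, S, 2000, pose = TRUE, seed = 12)
  fit <- iterative_mean_cov(sample_gaussian_state(spec))

  P <- centering_projector(N)
  SP <- P %*% S %*% P  # centering removes the ones-direction of the generator
  expect_lt(norm(fit$cov - SP, "F") / norm(SP, "F"), 0.10)
  # top-5 eigenvalue recovery
  ev_fit <- sort(eigen(fit$cov, symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)[1:5]
  ev_gen <- sort(eigen(SP, symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)[1:5]
  expect_lt(max(abs(ev_fit - ev_gen) / ev_gen), 0.10)
  # ones vector sits in the null space of the estimated covariance
  expect_lt(abs(min(eigen(fit$cov, symmetric = TRUE, only.values = TRUE)$values)),
            1e-10)
  expect_lt(max(abs(colMeans(fit$mean))), 1e-10)
  # objective (negative log-likelihood) non-increasing after the warm-up sweep
  obj <- attr(fit, "objective")
  expect_true(all(diff(obj[-1]) <= 1e-6 * max(1, abs(obj[2]))))

  # mean recovered up to a rotation: aligning generator mean to the fit is tight
  mu_al <- align_frame(mu, fit)
  expect_lt(sqrt(mean((mu_al - fit$mean)^2)), 0.05)
})

test_that("iterative estimation handles degenerate and tolerance edge cases", {
  set.seed(13)
  f <- random_mean(6)
  posed <- lapply(1:40, function(i) apply_rigid(f))
  fit <- iterative_mean_cov(as_traj(posed))
  ev <- eigen(fit$cov, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(max(abs(ev)), 1e-10)  # identical frames: zero shape variance
  expect_lt(sqrt(mean((align_frame(f, fit) - fit$mean)^2)), 1e-6)

  spec <- gaussian_state_spec(random_mean(5), diag(0.05, 5), 200, seed = 14)
  tr <- sample_gaussian_state(spec)
  f1 <- iterative_mean_cov(tr, tol = 1e-8)
  f2 <- iterative_mean_cov(tr, tol = 1e-7)
  expect_lt(max(abs(f1$mean - f2$mean)), 10 * 1e-7)

  expect_error(iterative_mean_cov(as_traj(f)), "at least 2")
})

test_that("rigid-motion invariance of the Mahalanobis distance holds", {
  set.seed(15)
  N <- 7
  ref <- shape_ref(random_mean(N), structured_cov(N, seed = 16))
  X <- ref$mean + 0.3 * matrix(rnorm(N * 3), N, 3)
  d0 <- mahalanobis_sq(align_frame(X, ref), ref)
  for (i in 1:20) {
    d <- mahalanobis_sq(align_frame(apply_rigid(X), ref), ref)
    expect_equal(d, d0, tolerance = 1e-8)
  }
})
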