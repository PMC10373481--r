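make_model <- function(seed = 41, N = 8, n_per = 100) {
  data <- two_state_data(N = N, n_per = n_per, seed = seed)
  train_poslda(data$traj, data$labels, 1, 2)
}

test_that("the coordinate is linear near the reference along its own direction", {
  m <- make_model()
  alpha <- 1e-3
  f <- m$ref$mean + alpha * matrix(m$v, ncol = 3)
  expect_equal(compute_cv(f, m), alpha, tolerance = 1e-4)
  expect_equal(compute_cv(m$ref$mean, m), 0, tolerance = 1e-12)
})

test_that("numerical gradient matches oracles and stays bounded", {
  m <- make_model(seed = 42)
  set.seed(43)
  f <- m$ref$mean + 0.2 * matrix(rnorm(length(m$v)), ncol = 3)
  f <- apply_rigid(f)
  g <- cv_gradient(f, m, step = 1e-4)
  expect_true(all(is.finite(g)))
  expect_lte(sqrt(sum(g^2)), 2 * sqrt(sum(m$v^2)))

  # Richardson-extrapolated oracle from steps h and h/2
  g1 <- cv_gradient(f, m, step = 1e-4)
  g2 <- cv_gradient(f, m, step = 5e-5)
  richardson <- (4 * g2 - g1) / 3
  expect_lt(max(abs(g - richardson)) / max(abs(richardson)), 1e-6)

  # directional consistency against a plain difference quotient
  u <- matrix(rnorm(length(m$v)), ncol = 3)
  u <- u / sqrt(sum(u^2))
  h <- 1e-4
  dd <- (compute_cv(f + h * u, m) - compute_cv(f - h * u, m)) / (2 * h)
  expect_equal(sum(g * u), dd, tolerance = 1e-6)

  # work along a short path reproduces the change in l
  set.seed(44)
  dir <- matrix(rnorm(length(m$v)), ncol = 3)
  dir <- dir / sqrt(sum(dir^2))
  n_seg <- 20
  step <- 0.01
  l_start <- compute_cv(f, m)
  work <- 0
  fc <- f
  for (i in seq_len(n_seg)) {
    gmid <- cv_gradient(fc + 0.5 * step * dir, m)
    work <- work + sum(gmid * dir) * step
    fc <- fc + step * dir
  }
  expect_equal(work, compute_cv(fc, m) - l_start,
               tolerance = 0.01 * max(abs(work), 0.01))
})

test_that("gradient at the reference is the coefficient field for isotropic covariance", {
  # shape-space direction: orthogonal to translations and rotations of mu
  set.seed(45)
  N <- 6
  mu <- random_mean(N)
  Ts <- cbind(c(rep(1, N), rep(0, 2 * N)), c(rep(0, N), rep(1, N), rep(0, N)),
              c(rep(0, 2 * N), rep(1, N)))
  Lx <- matrix(c(0, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3, byrow = TRUE)
  Ly <- matrix(c(0, 0, 1, 0, 0, 0, -1, 0, 0), 3, 3, byrow = TRUE)
  Lz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE)
  B <- qr.Q(qr(cbind(Ts, c(mu %*% t(Lx)), c(mu %*% t(Ly)), c(mu %*% t(Lz)))))
  v <- rnorm(3 * N)
  v <- v - B %*% (t(B) %*% v)
  v <- as.numeric(v / sqrt(sum(v^2)))
  model <- structure(list(v = v, ref = shape_ref(mu, diag(N)), sign = 1,
                          states = c(a = 1, b = 2),
                          meta = list(n_particles = N)),
                     class = "poslda_model")
  g <- cv_gradient(mu, model, step = 1e-4)
  expect_lt(max(abs(g - matrix(v, ncol = 3))), 1e-6)
})

test_that("well-tempered hills shrink against the scalar fixed-point oracle", {
  h <- 0.3
  sigma <- 0.2
  gamma <- 5
  temp <- 300
  kbdt <- 0.001987204259 * (gamma - 1) * temp
  hills <- NULL
  V_oracle <- 0
  for (i in 1:40) {
    hills <- wtmetad_update(hills, 0, height = h, sigma = sigma, gamma = gamma,
                            temperature = temp, time = i)
    expect_equal(hills$height[i], h * exp(-V_oracle / kbdt), tolerance = 1e-12)
    V_oracle <- V_oracle + h * exp(-V_oracle / kbdt)
  }
  expect_equal(wtmetad_bias(hills, 0), V_oracle, tolerance = 1e-12)
  expect_equal(hills$height[1], h)          # first hill at full height
  expect_true(all(diff(hills$height) < 0))  # monotone shrinking

  # enormous gamma: plain metadynamics, constant heights
  hills2 <- NULL
  for (i in 1:5)
    hills2 <- wtmetad_update(hills2, 0, height = h, sigma = sigma,
                             gamma = 1e9, temperature = temp)
  expect_equal(hills2$height, rep(h, 5), tolerance = 1e-6)

  expect_error(wtmetad_update(NULL, 0, height = h, sigma = sigma, gamma = 1),
               "gamma")
})

test_that("hill summation matches a brute-force oracle", {
  set.seed(46)
  hills <- tibble::tibble(time = 1:100, center = runif(100, -3, 3),
                          height = runif(100, 0.01, 0.3),
                          width = runif(100, 0.1, 0.5))
  Q <- runif(25, -4, 4)
  oracle <- sapply(Q, function(q)
    sum(hills$height * exp(-(q - hills$center)^2 / (2 * hills$width^2))))
  expect_identical(wtmetad_bias(hills, Q), oracle)
  expect_identical(wtmetad_bias(NULL, Q), rep(0, length(Q)))
  expect_equal(wtmetad_bias(hills[1, ], hills$center[1]), hills$height[1])
})

test_that("OPES bias follows the closed form, stays capped, and flattens", {
  st <- opes_state(gamma = 8, deltaE = 10, sigma = 0.1, temperature = 300,
                   range = c(0, 1), ngrid = 200)
  expect_equal(opes_bias(st, 0.3), 0)
  st <- opes_update(st, 0.5)
  # single kernel: hand-computed expression
  kT <- 0.001987204259 * 300
  pref <- (1 - 1 / 8) * kT
  eps <- exp(-10 / pref)
  q <- seq(0, 1, length.out = 200)
  Z <- mean(exp(-(q - 0.5)^2 / (2 * 0.1^2))) * 1
  hand <- pref * (log(1 / Z + eps) - log(eps))
  expect_equal(opes_bias(st, 0.5), min(hand, 10), tolerance = 1e-10)

  # uniform deposition flattens the bias over the interior
  set.seed(47)
  st2 <- opes_state(gamma = 8, deltaE = 10, sigma = 0.1, temperature = 300,
                    range = c(0, 1), ngrid = 200)
  qs <- rep(seq(0.025, 0.975, length.out = 40), length.out = 10000)
  for (q_i in qs) st2 <- opes_update(st2, q_i)
  grid <- seq(0.1, 0.9, length.out = 81)
  b <- opes_bias(st2, grid)
  expect_lt(diff(range(b)), 0.1 * 10)
  expect_true(all(b <= 10 + 1e-9))
  expect_true(all(b >= 0))

  # serialized kernels re-evaluate to the same bias
  st3 <- st2
  reeval <- function(kernels, sum_w, Q) {
    p <- colSums(kernels$weight *
                   exp(-outer(kernels$center, Q, "-")^2 /
                         (2 * kernels$width^2))) / sum_w
    qq <- seq(0, 1, length.out = 200)
    pz <- colSums(kernels$weight *
                    exp(-outer(kernels$center, qq, "-")^2 /
                          (2 * kernels$width^2))) / sum_w
    Z <- mean(pz) * 1
    pmin(pmax(pref * (log(p / Z + eps) - log(eps)), 0), 10)
  }
  expect_equal(reeval(st3$kernels, st3$sum_w, grid), b, tolerance = 1e-10)

  expect_error(opes_state(gamma = 8, deltaE = 0, sigma = 0.1), "deltaE")
  expect_error(opes_state(gamma = 1, deltaE = 1, sigma = 0.1), "gamma")
})

test_that("wall potential and its derivative are exact", {
  w <- wall_potential(c(0, 5, 6, -16), lower = -15, upper = 5, kappa = 125)
  expect_equal(w$energy, c(0, 0, 125, 125))
  expect_equal(w$deriv[1:2], c(0, 0))
  # derivative matches finite differences
  for (q in c(-16.3, -15.0001, 2, 5.3, 7)) {
    h <- 1e-7
    fd <- (wall_potential(q + h, -15, 5, 125)$energy -
           wall_potential(q - h, -15, 5, 125)$energy) / (2 * h)
    expect_equal(wall_potential(q, -15, 5, 125)$deriv, fd, tolerance = 1e-6)
  }
  expect_error(wall_potential(0, 5, -15, 125), "lower < upper")
})

test_that("bias-to-FES inversion is exact for zero and known bias", {
  q <- seq(-2, 2, length.out = 101)
  flat <- fes_from_bias(q, rep(0, 101), gamma = 5)
  expect_true(all(flat$F == 0))
  V <- 1.5 * exp(-q^2)
  fes <- fes_from_bias(q, V, gamma = 5)
  expect_equal(fes$F, 5 / 4 * (max(V) - V), tolerance = 1e-12)
  expect_equal(min(fes$F), 0)
})
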