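test_that("scatter matrices match a brute-force double loop and decompose", {
  set.seed(31)
  N <- 4
  n <- 20
  X <- matrix(rnorm(n * 3 * N), n)
  labels <- rep(1:2, each = n / 2)
  sc <- scatter_matrices(traj_from_matrix(X, N), labels)

  # element-by-element brute force
  m <- colMeans(X)
  Sw <- matrix(0, 3 * N, 3 * N)
  Sb <- matrix(0, 3 * N, 3 * N)
  for (s in 1:2) {
    Xi <- X[labels == s, , drop = FALSE]
    mi <- colMeans(Xi)
    for (r in seq_len(nrow(Xi))) Sw <- Sw + outer(Xi[r, ] - mi, Xi[r, ] - mi)
    Sb <- Sb + nrow(Xi) * outer(mi - m, mi - m)
  }
  expect_equal(sc$S_w, Sw, tolerance = 1e-10)
  expect_equal(sc$S_b, Sb, tolerance = 1e-10)

  # S_w + S_b equals the total scatter
  St <- crossprod(sweep(X, 2, m))
  expect_lt(norm(sc$S_w + sc$S_b - St, "F") / norm(St, "F"), 1e-6)
  expect_lt(max(abs(sc$S_w - t(sc$S_w))), 1e-8)

  # equal clusters with equal means: between-scatter vanishes
  sc0 <- scatter_matrices(traj_from_matrix(rbind(X[1:10, ], X[1:10, ]), N), labels)
  expect_lt(max(abs(sc0$S_b)), 1e-10)

  # unweighted S_b rescales but leaves the two-class direction unchanged
  scu <- scatter_matrices(traj_from_matrix(X, N), labels,
                          population_weighted = FALSE)
  expect_equal(scu$S_b * 10, sc$S_b, tolerance = 1e-10)
  vw <- lda_direction(sc)
  vu <- lda_direction(scu)
  expect_gt(abs(sum(vw * vu)), 1 - 1e-10)
})

test_that("discriminant direction matches the Fisher oracle on 50 instances", {
  set.seed(32)
  worst_ns <- 1
  worst_sg <- 1
  for (rep in 1:50) {
    N <- 4
    n <- 30
    X1 <- matrix(rnorm(n * 3 * N), n) %*% diag(runif(3 * N, 0.5, 2))
    X2 <- sweep(matrix(rnorm(n * 3 * N), n) %*% diag(runif(3 * N, 0.5, 2)),
                2, rnorm(3 * N) * 0.5, `+`)
    lab <- rep(1:2, each = n)
    sc <- scatter_matrices(traj_from_matrix(rbind(X1, X2), N), lab)
    v <- lda_direction(sc)
    dmu <- c(sc$cluster_means[["1"]]) - c(sc$cluster_means[["2"]])
    vf <- solve(sc$S_w, dmu)
    worst_ns <- min(worst_ns, abs(sum(v * vf)) / sqrt(sum(v^2) * sum(vf^2)))

    # singular instance: data confined to a 5-dim subspace
    k <- 5
    B <- qr.Q(qr(matrix(rnorm(3 * N * k), 3 * N, k)))
    Y1 <- matrix(rnorm(n * k), n) %*% t(B)
    Y2 <- sweep(matrix(rnorm(n * k), n), 2, rnorm(k), `+`) %*% t(B)
    scs <- scatter_matrices(traj_from_matrix(rbind(Y1, Y2), N), lab)
    vs <- lda_direction(scs)
    expect_lt(sqrt(sum((vs - B %*% (t(B) %*% vs))^2)), 1e-8)  # stays in subspace
    Sw_r <- t(B) %*% scs$S_w %*% B
    dmu_r <- t(B) %*% (c(scs$cluster_means[["1"]]) - c(scs$cluster_means[["2"]]))
    vr <- B %*% solve(Sw_r, dmu_r)
    worst_sg <- min(worst_sg, abs(sum(vs * vr)) / sqrt(sum(vs^2) * sum(vr^2)))
  }
  expect_gt(worst_ns, 1 - 1e-6)
  expect_gt(worst_sg, 1 - 1e-6)
})

test_that("exactly isotropic within-scatter gives the mean-difference direction", {
  set.seed(33)
  N <- 5
  m1 <- rnorm(3 * N)
  m2 <- rnorm(3 * N)
  m <- (m1 + m2) / 2
  sc <- structure(list(
    S_w = 2 * diag(3 * N),
    S_b = 10 * tcrossprod(m1 - m) + 10 * tcrossprod(m2 - m),
    cluster_means = list("1" = matrix(m1, ncol = 3), "2" = matrix(m2, ncol = 3)),
    global_mean = matrix(m, ncol = 3), n = c(10L, 10L), states = 1:2),
    class = "scatter_pair")
  v <- lda_direction(sc)
  dmu <- m1 - m2
  expect_gt(abs(sum(v * dmu)) / sqrt(sum(dmu^2)), 1 - 1e-8)
})

test_that("degenerate separation errors out", {
  set.seed(34)
  X <- matrix(rnorm(40 * 12), 40)
  sc <- scatter_matrices(traj_from_matrix(rbind(X, X), 4), rep(1:2, each = 40))
  expect_error(lda_direction(sc), "degenerate separation")
})

test_that("global alignment of a pooled pair reduces cleanly", {
  data <- two_state_data(N = 6, n_per = 60, seed = 35)
  ga <- global_align(data$traj, data$labels, c(1, 2))
  expect_lt(max(abs(colMeans(ga$ref$mean))), 1e-10)
  obj <- attr(iterative_mean_cov(subset_frames(data$traj, 1:60)), "objective")
  expect_true(all(diff(obj[-1]) <= 1e-6 * max(1, abs(obj[2]))))

  # pooling a state with itself equals fitting that state alone
  lab_same <- rep(c(1, 2), 60)[1:120]
  tr_same <- subset_frames(data$traj, rep(1:60, 2))
  ga_same <- global_align(tr_same, lab_same, c(1, 2))
  solo <- iterative_mean_cov(subset_frames(data$traj, 1:60))
  expect_equal(align_frame(ga_same$ref$mean, solo), solo$mean, tolerance = 1e-4)

  expect_error(global_align(data$traj, data$labels, c(1, 3)), "no frames")
})

test_that("training separates states, fixes signs, and is deterministic", {
  data <- two_state_data(N = 10, n_per = 200, seed = 36)
  m <- train_poslda(data$traj, data$labels, 1, 2)
  expect_equal(sqrt(sum(m$v^2)), 1, tolerance = 1e-12)
  expect_equal(compute_cv(m$ref$mean, m), 0, tolerance = 1e-12)

  pr <- project_cv(data$traj, m)
  la <- pr$l[data$labels == 1]
  lb <- pr$l[data$labels == 2]
  pooled_sd <- sqrt((var(la) + var(lb)) / 2)
  expect_lt(mean(la), 0)
  expect_gt(mean(lb), 0)
  expect_gt((mean(lb) - mean(la)) / pooled_sd, 4)
  expect_lt(max(la), min(lb))

  # 3-sd class intervals separate strictly inside the >= 6-sigma regime
  # (at exactly 6 sigma the intervals are tangent by construction)
  data8 <- two_state_data(N = 10, n_per = 200, sep = 1.6, seed = 361)
  m8 <- train_poslda(data8$traj, data8$labels, 1, 2)
  pr8 <- project_cv(data8$traj, m8)
  la8 <- pr8$l[data8$labels == 1]
  lb8 <- pr8$l[data8$labels == 2]
  expect_lt(mean(la8) + 3 * sd(la8), mean(lb8) - 3 * sd(lb8))

  # swapping the state roles flips the sign exactly
  m2 <- train_poslda(data$traj, data$labels, 2, 1)
  expect_identical(m$v, -m2$v)
  # identical rerun is bit-identical
  m3 <- train_poslda(data$traj, data$labels, 1, 2)
  expect_identical(m$v, m3$v)
  expect_identical(m$ref$mean, m3$ref$mean)
})

test_that("projection is invariant to rigid motions of the input", {
  data <- two_state_data(N = 8, n_per = 100, seed = 37)
  m <- train_poslda(data$traj, data$labels, 1, 2)
  set.seed(38)
  for (i in 1:20) {
    f <- get_frame(data$traj, sample(n_frames(data$traj), 1))
    l0 <- compute_cv(f, m)
    expect_equal(compute_cv(apply_rigid(f), m), l0, tolerance = 1e-8)
  }
})

test_that("tidy, glance and model round trips preserve the model", {
  data <- two_state_data(N = 6, n_per = 60, seed = 39)
  m <- train_poslda(data$traj, data$labels, 1, 2)
  td <- tidy(m)
  expect_named(td, c("particle", "vx", "vy", "vz", "magnitude"))
  expect_equal(sum(td$magnitude^2), 1, tolerance = 1e-12)
  gl <- glance(m)
  expect_equal(gl$n_a, 60L)
  expect_equal(gl$norm_v, 1, tolerance = 1e-12)

  path <- tempfile(fileext = ".json")
  write_lda_model(m, path)
  m2 <- read_lda_model(path)
  expect_equal(m2$v, m$v, tolerance = 1e-14)
  expect_equal(m2$ref$mean, m$ref$mean, tolerance = 1e-14)
  pr <- project_cv(data$traj, m)
  pr2 <- project_cv(data$traj, m2)
  expect_equal(pr2$l, pr$l, tolerance = 1e-10)

  cpath <- tempfile(fileext = ".txt")
  write_cv_coeffs(m, cpath)
  coefs <- as.matrix(read.table(cpath))
  expect_equal(c(coefs), m$v, tolerance = 1e-14, ignore_attr = TRUE)
})
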