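test_that("consecutive distances and speed match hand values", {
  X <- rbind(c(0, 0), c(3, 4), c(3, 0))
  expect_equal(consecutive_distances(X), c(5, 4))
  expect_equal(path_speed(X), 4.5)
  expect_equal(consecutive_distances(rbind(c(0, 0), c(3, 4))), 5)
  expect_equal(consecutive_distances(matrix(1, 4, 3)), rep(0, 3))
  # collinear equally spaced: speed equals the spacing
  expect_equal(path_speed(cbind(seq(0, 10, by = 2.5), 0)), 2.5)
  expect_error(path_speed(matrix(0, 1, 2)), "too short")
})

test_that("affine projection finds the right rank and preserves distances", {
  set.seed(42)
  B <- matrix(rnorm(300 * 2), 300, 2)
  Z <- matrix(rnorm(3 * 2), 3, 2)
  X <- Z %*% t(B) + matrix(rnorm(300), 3, 300, byrow = TRUE)  # 3 pts, 2-d hull
  pr <- project_to_affine_subspace(X)
  expect_identical(pr$d, 2L)
  expect_equal(as.matrix(dist(pr$coords)), as.matrix(dist(X)), tolerance = 1e-9)

  expect_identical(project_to_affine_subspace(matrix(5, 4, 10))$d, 0L)

  for (seed in 1:10) {
    X <- rand_points(sample(3:12, 1), sample(2:50, 1), seed)
    pr <- project_to_affine_subspace(X)
    expect_lte(pr$d, min(nrow(X) - 1L, ncol(X)))
    expect_equal(as.matrix(dist(pr$coords)), as.matrix(dist(X)),
                 tolerance = 1e-9)
  }
})

test_that("minimum-volume ellipsoid matches closed forms", {
  # 1-d pair: the spanning interval
  e1 <- mvee(matrix(c(0, 7.5), 2, 1))
  expect_equal(e1$volume, 7.5)
  # unit-square corners: circumscribed disk of radius sqrt(2)/2, area pi/2
  e2 <- mvee(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
  expect_equal(e2$volume, pi / 2, tolerance = 1e-6)
  expect_equal(e2$center, c(0.5, 0.5), tolerance = 1e-6)
  # degenerate zero-dimensional input
  e0 <- mvee(matrix(numeric(0), 3, 0))
  expect_equal(e0$volume, 0)
  expect_error(mvee(rand_points(3, 3, 1)), "at least d \\+ 1")
})

test_that("ellipsoid contains every point and verifies optimality", {
  for (seed in 1:25) {
    set.seed(seed)
    T <- sample(4:10, 1)
    d <- sample(1:min(4, T - 1), 1)
    X <- rand_points(T, d, seed + 100)
    ell <- mvee(X)
    C <- sweep(X, 2, ell$center)
    expect_lte(max(rowSums((C %*% ell$shape) * C)), 1 + 1e-6)
    expect_true(verify_mvee_optimality(X, ell, tol = 1e-3)$pass)
  }
})

test_that("ellipsoid volume agrees with a high-precision oracle", {
  for (seed in 1:30) {
    set.seed(seed)
    T <- sample(5:10, 1)
    d <- sample(2:4, 1)
    X <- rand_points(T, d, seed + 500)
    v <- mvee(X)$volume
    v_oracle <- oracle_mvee(X)$volume
    expect_equal(v, v_oracle, tolerance = 1e-4)
  }
})

test_that("ellipsoid volume agrees with an independent implementation", {
  skip_if_not_installed("cluster")
  for (seed in 1:10) {
    X <- rand_points(8, 3, seed + 900)
    eh <- cluster::ellipsoidhull(X, tol = 1e-9, maxit = 10000)
    # ellipsoidhull: (x - loc)' cov^{-1} (x - loc) <= d2
    v_ref <- exp(log(2) - log(3) + 3 / 2 * log(pi) - lgamma(3 / 2) +
                   1.5 * log(eh$d2) + 0.5 * determinant(eh$cov)$modulus)
    expect_equal(mvee(X)$volume, as.numeric(v_ref), tolerance = 1e-3)
  }
})

test_that("adding a point outside the ellipsoid strictly grows the volume", {
  for (seed in 1:10) {
    X <- rand_points(8, 3, seed)
    ell <- mvee(X)
    outside <- ell$center + 5 * (X[1, ] - ell$center)
    expect_gt(mvee(rbind(X, outside))$volume, ell$volume)
  }
})

test_that("normalized volume has the stated closed forms and homogeneity", {
  # sphere of radius r: dim_root = U_d^(1/d) * r
  set.seed(9)
  d <- 3; r <- 2.5
  dirs <- matrix(rnorm(40 * d), 40, d)
  sphere <- r * dirs / sqrt(rowSums(dirs^2))
  ell <- mvee(sphere)
  ub <- pi^(d / 2) / gamma(d / 2 + 1)
  expect_equal(normalized_volume(ell, 40, "dim_root"), ub^(1 / d) * r,
               tolerance = 1e-4)
  expect_equal(normalized_volume(ell, 40, "per_chunk"),
               normalized_volume(ell, 40, "dim_root") / 40)
  sq <- mvee(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
  expect_equal(normalized_volume(sq, 4, "raw"), pi / 2, tolerance = 1e-6)
  # scaling points by c scales dim_root by c
  X <- rand_points(9, 3, 4)
  e1 <- mvee(X); e2 <- mvee(X * 3)
  expect_equal(normalized_volume(e2, 9, "dim_root"),
               3 * normalized_volume(e1, 9, "dim_root"), tolerance = 1e-6)
})

test_that("exact path solver matches brute-force enumeration", {
  for (seed in 1:30) {
    set.seed(seed)
    T <- sample(4:9, 1)
    X <- rand_points(T, 2, seed + 300)
    ex <- min_path_exact(X)
    bf <- brute_force_min_path(X)
    expect_equal(ex$total_length, bf$total_length, tolerance = 1e-12)
    expect_identical(ex$order, bf$order)
    expect_identical(ex$order[1], 1L)
    expect_identical(ex$order[T], T)
  }
})

test_that("trivial and single-candidate path cases", {
  X2 <- rbind(c(0, 0), c(3, 4))
  s2 <- min_path_exact(X2)
  expect_identical(s2$order, c(1L, 2L))
  expect_equal(s2$total_length, 5)
  expect_identical(s2$solver, "trivial")
  X3 <- rbind(c(0, 0), c(5, 1), c(1, 0))
  s3 <- min_path_exact(X3)
  expect_identical(s3$order, 1:3)
  expect_identical(s3$solver, "exact")
  expect_error(min_path_exact(rand_points(20, 2, 1)), "exact_max")
})

test_that("heuristic is bounded by exact below and observed order above", {
  for (seed in 1:25) {
    set.seed(seed)
    T <- sample(5:14, 1)
    X <- rand_points(T, 3, seed + 700)
    h <- min_path_heuristic(X, restarts = 10, seed = 99)
    ex <- min_path_exact(X, exact_max = 12)
    expect_gte(h$total_length, ex$total_length - 1e-9)
    expect_lte(h$total_length, observed_length(X) + 1e-9)
  }
  # collinear sorted points: identity is already optimal
  Xl <- cbind(0:7, 0)
  expect_equal(min_path_heuristic(Xl, 5, 1)$total_length, 7)
  # fixed seed gives identical solutions
  X <- rand_points(18, 3, 11)
  h1 <- min_path_heuristic(X, 10, 123)
  h2 <- min_path_heuristic(X, 10, 123)
  expect_identical(h1$order, h2$order)
  expect_identical(h1$total_length, h2$total_length)
})

test_that("minimum required speed is path length over T - 1 and order-free", {
  X2 <- rbind(c(0, 0), c(4, 0))
  expect_equal(min_required_speed(min_path_exact(X2), 2), 4)
  Xl <- cbind(seq(0, 12, by = 1.5), 0)
  expect_equal(min_required_speed(min_path_exact(Xl, exact_max = 12), nrow(Xl)), 1.5)
  # shuffling interior points leaves the minimum unchanged
  set.seed(3)
  X <- rand_points(9, 2, 31)
  perm <- c(1, 1 + sample(7), 9)
  m1 <- min_required_speed(min_path_exact(X), 9)
  m2 <- min_required_speed(min_path_exact(X[perm, ]), 9)
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("circuitousness contracts hold", {
  expect_equal(as.numeric(circuitousness(1.5, 1.5)), 1)
  c0 <- circuitousness(0, 0)
  expect_equal(as.numeric(c0), 1)
  expect_true(isTRUE(attr(c0, "degenerate")))
  expect_error(circuitousness(1, 0), "inconsistency")
  # T = 3 on a line with interior out of order: single admissible order
  X <- cbind(c(0, 2, 1), 0)
  f <- extract_features(semantic_path(X))
  expect_equal(f$speed, 1.5)
  expect_equal(f$circuitousness, 1)
  # 5-point configuration vs permutation-enumeration oracle
  for (seed in 1:10) {
    X <- rand_points(5, 2, seed + 40)
    f <- extract_features(semantic_path(X))
    oracle <- observed_length(X) / brute_force_min_path(X)$total_length
    expect_equal(f$circuitousness, oracle, tolerance = 1e-12)
  }
})

test_that("feature extraction satisfies the log identity and solver tags", {
  for (seed in 1:10) {
    X <- rand_points(sample(4:12, 1), 4, seed + 60)
    f <- extract_features(semantic_path(X))
    expect_lt(abs(log(f$speed) - log(f$circuitousness) -
                    log(f$min_required_speed)), 1e-9)
    expect_identical(f$solver, "exact")
    expect_gte(f$circuitousness, 1 - 1e-9)
  }
  f <- extract_features(semantic_path(rand_points(20, 5, 1)))
  expect_identical(f$solver, "heuristic")
  expect_gte(f$circuitousness, 1 - 1e-9)  # identity order is a candidate
  fshort <- extract_features(semantic_path(matrix(0, 1, 4)))
  expect_true(is.na(fshort$speed))
  expect_true("too_short_for_speed" %in% fshort$flags)
})

test_that("features are invariant under rigid motion and homogeneous in scale", {
  for (seed in 1:12) {
    set.seed(seed)
    T <- sample(5:12, 1)
    d <- sample(2:4, 1)
    X <- rand_points(T, d, seed + 80)
    f0 <- extract_features(semantic_path(X))
    R <- rand_rotation(d, seed)
    shift <- matrix(rnorm(d, sd = 5), T, d, byrow = TRUE)
    f1 <- extract_features(semantic_path(X %*% R + shift))
    expect_equal(f1$speed, f0$speed, tolerance = 1e-8)
    expect_equal(f1$norm_volume, f0$norm_volume, tolerance = 1e-8)
    expect_equal(f1$min_required_speed, f0$min_required_speed, tolerance = 1e-8)
    expect_equal(f1$circuitousness, f0$circuitousness, tolerance = 1e-8)

    cc <- 0.5 + 3 * runif(1)
    f2 <- extract_features(semantic_path(X * cc))
    expect_equal(f2$speed, cc * f0$speed, tolerance = 1e-8)
    expect_equal(f2$min_required_speed, cc * f0$min_required_speed,
                 tolerance = 1e-8)
    expect_equal(f2$norm_volume, cc * f0$norm_volume, tolerance = 1e-8)
    expect_equal(f2$circuitousness, f0$circuitousness, tolerance = 1e-8)

    # interior permutation: speed changes, min speed and volumes do not
    perm <- c(1, 1 + sample(T - 2), T)
    f3 <- extract_features(semantic_path(X[perm, ]))
    expect_equal(f3$min_required_speed, f0$min_required_speed, tolerance = 1e-9)
    expect_equal(f3$norm_volume, f0$norm_volume, tolerance = 1e-8)
    expect_equal(f3$raw_volume, f0$raw_volume, tolerance = 1e-7)
  }
})
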