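test_that("membership update reproduces hand-computed columns", {
  # x = 10 equidistant from (0, 20): symmetric memberships
  expect_equal(as.vector(fcm_membership(c(0, 20), 10)), c(0.5, 0.5))
  # x = 5: u1 = 1/(1 + (5/15)^2) = 0.9
  expect_equal(as.vector(fcm_membership(c(0, 20), 5)), c(0.9, 0.1))
  # pixel on a center: zero-distance convention
  expect_equal(as.vector(fcm_membership(c(0, 20), 0)), c(1, 0))
  # coincident centers on the pixel: first one wins
  expect_equal(as.vector(fcm_membership(c(7, 7), 7)), c(1, 0))
})

test_that("membership columns always sum to one (property)", {
  set.seed(42)
  for (k in 1:20) {
    cc <- sample(2:5, 1)
    m <- runif(1, 1.2, 3)
    x <- runif(12, 0, 255)
    x[1] <- 0 # exercise the zero-distance path sometimes
    u <- fcm_membership(c(0, runif(cc - 1, 1, 255)), x, m)
    expect_equal(colSums(u), rep(1, 12), tolerance = 1e-9)
    expect_true(all(u >= 0 & u <= 1))
  }
})

test_that("membership agrees with a literal transcription of the update", {
  set.seed(9)
  centers <- c(12, 130, 240)
  x <- runif(30, 0, 255)
  u <- fcm_membership(centers, x, m = 2.4)
  for (j in seq_along(x))
    expect_equal(u[, j], oracle_membership_column(x[j], centers, 2.4),
                 tolerance = 1e-12)
})

test_that("objective reproduces hand values", {
  expect_equal(fcm_objective(c(0, 255), c(0, 255)), 0)
  expect_equal(fcm_objective(c(0, 20), 10), 50) # 2 * 0.25 * 100
  gg <- grid_graph(lump_size = 8)
  expect_equal(fcm_objective(c(0, 127, 255), gg$image), 0)
})

test_that("objective agrees with the closed-form pair oracle", {
  set.seed(13)
  x <- runif(40, 0, 255)
  for (k in 1:10) {
    v <- sort(runif(2, 0, 255))
    expect_equal(fcm_objective(v, x), oracle_pair_objective(x, v[1], v[2]),
                 tolerance = 1e-10)
  }
})

test_that("center update is the fuzzified weighted mean", {
  # hard memberships at m = 2 reduce to per-cluster arithmetic means
  u <- rbind(c(1, 1, 0), c(0, 0, 1))
  x <- c(10, 30, 100)
  expect_equal(fcm_centers(u, x), c(20, 100))
  # uniform memberships pull all centers to the grand weighted mean
  u2 <- matrix(0.5, 2, 2)
  expect_equal(fcm_centers(u2, c(0, 100)), c(50, 50))
  # single pixel: every center equals it
  expect_equal(fcm_centers(matrix(c(0.3, 0.7)), 42), c(42, 42))
  # convexity: centers stay inside the data range
  set.seed(4)
  for (k in 1:10) {
    x <- runif(15, 0, 255)
    u <- fcm_membership(runif(3, 0, 255), x)
    v <- fcm_centers(u, x)
    expect_true(all(v >= min(x) & v <= max(x)))
  }
  expect_error(fcm_centers(rbind(c(1, 1), c(0, 0)), c(1, 2)), "degenerate")
})

test_that("run_fcm solves the separable two-block image exactly", {
  img <- cbind(matrix(0, 4, 4), matrix(255, 4, 4))
  fit <- run_fcm(img, 2, seed = 1)
  expect_true(fit$converged)
  expect_equal(sort(fit$centers), c(0, 255), tolerance = 1e-6)
  expect_lt(fit$objective, 1e-6)
})

test_that("run_fcm objective trace is monotonically non-increasing", {
  set.seed(77)
  for (k in 1:50) {
    img <- matrix(runif(36, 0, 255), 6, 6)
    fit <- run_fcm(img, sample(2:4, 1), max_iter = 40,
                   seed = sample.int(1e6, 1))
    expect_true(all(diff(fit$objective_trace) <= 1e-6 *
                      pmax(fit$objective_trace[-length(fit$objective_trace)], 1)))
  }
})

test_that("run_fcm attains the brute-force global minimum for c = 2", {
  for (s in 1:4) {
    img <- random_tiny_image(10, seed = 100 + s)
    jgrid <- brute_force_min_j(as.numeric(img), res = 0.5)
    jfcm <- min(vapply(1:5, function(i)
      run_fcm(img, 2, seed = i)$objective, numeric(1)))
    # continuous optimization must match (or beat) the 0.5-level grid
    expect_lte(jfcm, jgrid + 1e-6)
    # and the grid can only be better by its own resolution gap
    expect_lt(jgrid - jfcm, 2)
  }
})

test_that("run_fcm segments the clean grid graph perfectly", {
  gg <- grid_graph(lump_size = 16)
  fit <- run_fcm(gg$image, 3, seed = 5)
  pred <- hard_assign(gg$image, centers = fit$centers)
  expect_equal(seg_accuracy(pred, gg$labels), 1)
})

test_that("SFCM suppression rule and limits", {
  u <- matrix(c(0.6, 0.3, 0.1), 3, 1)
  expect_equal(as.vector(hafsaseg:::suppress_membership(u, 0.5)),
               c(0.8, 0.15, 0.05))
  expect_equal(colSums(hafsaseg:::suppress_membership(u, 0.3)), 1)
  # alpha = 0 hardens the winner
  expect_equal(as.vector(hafsaseg:::suppress_membership(u, 0)), c(1, 0, 0))
  expect_error(run_sfcm(matrix(1:9, 3), 2, alpha = 1.5), "\\[0, 1\\]")
})

test_that("SFCM with alpha = 1 reproduces the FCM trajectory", {
  img <- grid_graph(lump_size = 4)$image
  noisy <- add_gaussian_noise(img, 0.05, seed = 3)
  f1 <- run_fcm(noisy, 3, seed = 10)
  f2 <- run_sfcm(noisy, 3, alpha = 1, seed = 10)
  expect_equal(f1$centers, f2$centers, tolerance = 1e-12)
  expect_equal(f1$objective_trace, f2$objective_trace, tolerance = 1e-12)
})

test_that("hard assignment: ties, identity, grid-graph partition", {
  # tie between centers 0 and 20 at x = 10 goes to the lower index
  expect_equal(as.vector(hard_assign(matrix(10), centers = c(0, 20))), 1L)
  u <- rbind(c(1, 0), c(0, 1))
  expect_equal(as.vector(hard_assign(matrix(c(5, 250), 1), membership = u)),
               c(1L, 2L))
  gg <- grid_graph(lump_size = 8)
  cmap <- hard_assign(gg$image, centers = c(0, 127, 255))
  expect_identical(cmap, gg$labels)
  expect_error(hard_assign(matrix(1)), "exactly one")
})
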