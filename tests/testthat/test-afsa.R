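test_that("move_toward follows the unit vector scaled by xi * step", {
  expect_equal(move_toward(c(0, 0), c(3, 4), step = 10, xi = 1), c(6, 8))
  expect_equal(move_toward(c(5, 5), c(100, 100), step = 10, xi = 0), c(5, 5))
  expect_equal(move_toward(c(7, 7), c(7, 7), step = 10), c(7, 7))
  set.seed(3)
  for (k in 1:20) {
    cur <- runif(3, 0, 255); tgt <- runif(3, 0, 255)
    out <- move_toward(cur, tgt, step = 12.8)
    expect_lte(sqrt(sum((out - cur)^2)), 12.8 + 1e-12)
    expect_true(all(out >= 0 & out <= 255))
  }
})

test_that("random_move is bounded per coordinate and clipped", {
  expect_equal(random_move(c(1, 2, 3), visual = 0), c(1, 2, 3))
  set.seed(8)
  for (k in 1:20) {
    cur <- runif(4, 0, 255)
    out <- random_move(cur, visual = 25.6)
    expect_true(all(abs(out - cur) <= 25.6 + 1e-12))
    expect_true(all(out >= 0 & out <= 255))
  }
})

test_that("cooling schedule is geometric with exact endpoints", {
  sch <- anneal_schedule(T0 = 1e4, T_end = 1e2, maxgen = 50)
  expect_equal(sch$q, 0.01^(1 / 50))
  expect_equal(sch$q, 0.912011, tolerance = 1e-6)
  expect_equal(cooling_temperature(sch, 0), 1e4)
  expect_equal(cooling_temperature(sch, 50), 1e2, tolerance = 1e-12)
  temps <- vapply(0:50, cooling_temperature, numeric(1), schedule = sch)
  expect_true(all(diff(temps) < 0))
  expect_equal(temps[-1] / temps[-51], rep(sch$q, 50), tolerance = 1e-12)
})

test_that("metropolis rule: unconditional downhill, calibrated uphill", {
  set.seed(1)
  expect_true(metropolis_accept(10, 10, temperature = 1))
  expect_true(all(vapply(1:50, function(i)
    metropolis_accept(10, runif(1, 0, 10), 1e-8), logical(1))))
  # acceptance frequency at delta J = k*T is exp(-1) within 3 binomial SE
  set.seed(202)
  n <- 1e4
  acc <- mean(vapply(seq_len(n), function(i)
    metropolis_accept(0, 5, temperature = 5), logical(1)))
  p <- exp(-1)
  expect_lt(abs(acc - p), 3 * sqrt(p * (1 - p) / n))
  # vanishing temperature rejects uphill moves
  set.seed(5)
  expect_false(any(vapply(1:1000, function(i)
    metropolis_accept(0, 1, temperature = 1e-4), logical(1))))
})

test_that("prey improves a monotone one-center problem and defaults to random", {
  params <- afsa_params()
  x <- 100 # single pixel, c = 1: J(v) = (v - 100)^2
  set.seed(21)
  out <- hafsaseg:::prey_step(0, fcm_objective(0, x), x, 2, params)
  expect_gt(out, 0)
  expect_lt(fcm_objective(out, x), fcm_objective(0, x))
  # unimprovable fish (J = 0): every candidate fails, random move results
  set.seed(22)
  out2 <- hafsaseg:::prey_step(c(0, 255), 0, c(0, 255), 2, params)
  expect_true(all(abs(out2 - c(0, 255)) <= params$visual + 1e-12))
})

test_that("swarm and follow fall through to prey when the test fails", {
  params <- afsa_params(delta = 0)
  x <- as.numeric(grid_graph(lump_size = 2)$image)
  positions <- rbind(c(10, 120, 250), c(0, 127, 255))
  foods <- apply(positions, 1, fcm_objective, image = x)
  # delta = 0: J(Vc)/num < 0 never holds, so both behaviors are prey
  set.seed(31)
  a <- hafsaseg:::swarm_step(1, positions, foods, x, 2, params)
  set.seed(31)
  b <- hafsaseg:::prey_step(positions[1, ], foods[1], x, 2, params)
  expect_identical(a, b)
  set.seed(31)
  f <- hafsaseg:::follow_step(1, positions, foods, x, 2, params)
  expect_identical(f, b)
})

test_that("follow moves toward the best visible partner when uncrowded", {
  params <- afsa_params(delta = 1, visual = 50)
  x <- as.numeric(grid_graph(lump_size = 2)$image)
  # partner sits at the optimum, fish nearby (within visual)
  positions <- rbind(c(20, 110, 240), c(0, 127, 255))
  foods <- apply(positions, 1, fcm_objective, image = x)
  set.seed(41)
  out <- hafsaseg:::follow_step(1, positions, foods, x, 2, params)
  set.seed(41)
  expected <- move_toward(positions[1, ], positions[2, ], params$step)
  expect_identical(out, expected)
  # a partner outside visual range is invisible: prey instead
  params2 <- afsa_params(delta = 1, visual = 5)
  set.seed(42)
  out2 <- hafsaseg:::follow_step(1, positions, foods, x, 2, params2)
  set.seed(42)
  expect_identical(out2,
                   hafsaseg:::prey_step(positions[1, ], foods[1], x, 2,
                                        params2))
})

test_that("greedy acceptance yields a non-increasing global best", {
  img <- add_gaussian_noise(grid_graph(lump_size = 4)$image, 0.05, seed = 2)
  res <- run_hafsa(img, 3, params = afsa_params(maxgen = 15), denoise = FALSE,
                   acceptance = "greedy", seed = 9)
  expect_true(all(diff(res$objective_trace) <= 0))
})
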