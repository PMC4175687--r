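test_that("Metropolis criterion honors the Boltzmann rule and its limits", {
  set.seed(1)
  expect_true(metropolis_accept(2e-19, 1e-19, 293))   # downhill: always
  expect_true(metropolis_accept(1e-19, 1e-19, 293))   # equal: exp(0) >= rho
  expect_false(metropolis_accept(1e-19, 2e-19, 0))    # T -> 0 rejects uphill
  # acceptance frequency of a fixed uphill step matches exp(-dE/kT)
  kB <- 1.38e-23
  dE <- kB * 293  # one thermal quantum
  acc <- mean(replicate(20000, metropolis_accept(0, dE, 293)))
  expect_equal(acc, exp(-1), tolerance = 0.02)
})

test_that("annealing rule cools by 0.9 unless energy dropped 10 percent", {
  # equal means: E > 0.9 E, so cool
  expect_equal(anneal_temperature(350, 1e-19, 1e-19), 315)
  # halved energy: no cooling
  expect_equal(anneal_temperature(350, 0.5e-19, 1e-19), 350)
  # floor is never crossed
  expect_equal(anneal_temperature(10.5, 1e-19, 1e-19), 10)
  expect_equal(anneal_temperature(10, 1e-19, 1e-19), 10)
})

test_that("zero-step simulation returns empty metrics and the input skeleton", {
  sim <- run_simulation(2686, "local", steps = 0, seed = 1)
  expect_identical(nrow(sim$metrics), 0L)
  expect_identical(sim$final$vertices, skeleton_from_bp(2686)$vertices)
})

test_that("fixed seed reproduces a run bit-identically", {
  a <- run_simulation(600, "local", steps = 2000, temperature = 293, seed = 5)
  b <- run_simulation(600, "local", steps = 2000, temperature = 293, seed = 5)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$final$vertices, b$final$vertices)
  c <- run_simulation(600, "local", steps = 2000, temperature = 293, seed = 6)
  expect_false(identical(a$metrics$accepted, c$metrics$accepted))
})

test_that("state is unchanged on rejected steps", {
  sim <- run_simulation(600, "crankshaft", steps = 4000, temperature = 150,
                        seed = 2)
  m <- sim$metrics
  rej <- which(m$accepted == 0 & m$knot_rejected == 0)
  rej <- rej[rej > 1]
  expect_gt(length(rej), 0)
  expect_identical(m$E[rej], m$E[rej - 1])
  expect_identical(m$Wr[rej], m$Wr[rej - 1])
})

test_that("energy trace is stationary at fixed temperature after warm-up", {
  sim <- run_simulation(600, "local", steps = 60000, temperature = 293, seed = 3)
  e <- sim$metrics$E[20001:60000]
  half <- length(e) %/% 2
  diff <- abs(mean(e[1:half]) - mean(e[(half + 1):length(e)]))
  # batch-means standard error accounts for the autocorrelation of E
  bm <- tapply(e, rep(1:20, each = length(e) %/% 20), mean)
  se_diff <- sd(bm) * sqrt(2 / 10)
  expect_lt(diff, 3 * se_diff)
})

test_that("displacement metrics average the moved-vertex distances", {
  p <- structure(list(kind = "local", moved = 1:3,
                      old_pos = matrix(0, 3, 3),
                      new_pos = matrix(c(1, 0, 0, 2, 0, 0, 3, 0, 0), 3, 3,
                                       byrow = TRUE)),
                 class = "move_proposal")
  dm <- displacement_metrics(p)
  expect_equal(dm$avg, 2)
  expect_equal(dm$distances, c(1, 2, 3))

  # identity proposal displaces nothing
  sk <- build_circular_skeleton(12, 1)
  pid <- apply_local_move(sk, 4, sk$vertices[4, ], 0, 0)
  expect_lt(displacement_metrics(pid)$avg, 1e-12)
})

test_that("slice report aggregates acceptance and accumulated displacement", {
  sim <- run_simulation(600, "local", steps = 5000, temperature = 293, seed = 7)
  sl <- slice_report(sim, 1000)
  expect_identical(nrow(sl), 5L)
  expect_identical(sum(sl$accepted), sum(sim$metrics$accepted))
  expect_equal(sum(sl$accepted) / 5000, mean(sim$metrics$accepted))
  # accumulated displacement counts accepted trials only
  m <- sim$metrics
  expect_equal(sum(sl$accum_disp), sum(m$avg_disp[m$accepted == 1]),
               tolerance = 1e-9)
  # partial trailing slice is flagged
  sl2 <- slice_report(sim, 1500)
  expect_identical(sl2$partial, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("annealing drives the temperature from start to floor", {
  sim <- run_simulation(600, "local", steps = 60000, anneal = c(350, 10),
                        seed = 9)
  T <- sim$metrics$T
  expect_equal(T[1], 350)
  expect_gte(min(T), 10)
  expect_equal(T[length(T)], 10)
  expect_true(all(diff(T) <= 0))
})

test_that("equilibrium detection finds the plateau of a synthetic decay", {
  n <- 60000
  e <- c(seq(10, 1, length.out = 20000), rep(1, n - 20000))
  m <- data.frame(step = 1:n, E = e)
  st <- equilibrium_step(m, trailing = 5000, final_window = 10000, tol = 0.10)
  # independent oracle: rolling trailing mean via stats::filter
  tm <- stats::filter(e, rep(1 / 5000, 5000), sides = 1)
  want <- which(!is.na(tm) & abs(tm - 1) <= 0.1)[1]
  expect_identical(st, as.integer(want))
  expect_error(equilibrium_step(m[1:3000, ], trailing = 5000,
                                final_window = 10000), "shorter")
})

test_that("trajectory frames are recorded at the requested stride", {
  sim <- run_simulation(600, "local", steps = 3000, temperature = 293,
                        seed = 11, traj_stride = 1000)
  expect_length(sim$frames, 3L)
  expect_identical(vapply(sim$frames, `[[`, integer(1), "step"),
                   c(1000L, 2000L, 3000L))
  for (f in sim$frames) expect_true(validate_skeleton(f$skeleton)$pass)
})
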