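test_that("bending energy of a regular polygon matches the closed form", {
  k <- physical_constants(T = 293)
  for (s in c(6, 20, 79)) {
    sk <- build_circular_skeleton(s, 112.2)
    closed <- 0.5 * k$k_B * k$T * k$alpha * s * (2 * pi / s)^2
    expect_equal(bending_energy(sk, k), closed, tolerance = 1e-12)
  }
  # prefactor scales with T; angles are scale-free
  sk <- build_circular_skeleton(12, 1)
  expect_identical(bending_energy(sk, physical_constants(T = 0)), 0)
  expect_equal(bending_energy(skeleton(2 * sk$vertices, l = 2, validate = FALSE), k),
               bending_energy(sk, k), tolerance = 1e-12)
})

test_that("linking-number deficit follows sigma * n_bp / helical_repeat", {
  k <- physical_constants(sigma = -0.04, helical_repeat = 10.5)
  lk <- delta_linking_number(2686, k)
  expect_equal(lk$Lk0, 2686 / 10.5, tolerance = 1e-12)
  expect_equal(lk$dLk, -0.04 * 2686 / 10.5, tolerance = 1e-12)
  expect_equal(delta_linking_number(2686, physical_constants(sigma = 0))$dLk, 0)
  # linear in sigma
  expect_equal(delta_linking_number(2686, physical_constants(sigma = -0.08))$dLk,
               2 * lk$dLk, tolerance = 1e-12)
})

test_that("torsional energy is the quadratic in the unabsorbed deficit", {
  k <- physical_constants()
  sk <- build_circular_skeleton(79, 112.2)
  expect_equal(torsional_energy(sk, k, dLk = -10.2, Wr = -10.2), 0)
  e1 <- torsional_energy(sk, k, dLk = -10.2, Wr = 0)
  # quadratic form: sqrt(2) scaling of the deficit doubles the energy
  e2 <- torsional_energy(sk, k, dLk = -10.2 * sqrt(2), Wr = 0)
  expect_equal(e2 / e1, 2, tolerance = 1e-12)
  # rigid motion leaves it unchanged (depends only on Wr, dLk, L)
  set.seed(4)
  vrot <- rotate_rigid(sk$vertices) + rep(1, 79) %o% c(3, -2, 7)
  expect_equal(torsional_energy(skeleton(vrot, l = sk$l, validate = FALSE),
                                k, dLk = -10.2, Wr = 0),
               e1, tolerance = 1e-9)
})

test_that("total energy decomposes exactly and respects sigma = 0", {
  sk <- build_circular_skeleton(79, 112.2)
  k0 <- physical_constants(sigma = 0)
  br <- total_energy(sk, k0, n_bp = 2686)
  expect_identical(br$E, br$E_b + br$E_t)
  expect_equal(br$E_t, 0)
  expect_equal(br$E, bending_energy(sk, k0), tolerance = 1e-12)

  k <- physical_constants()
  br2 <- total_energy(sk, k, n_bp = 2686)
  expect_identical(br2$E, br2$E_b + br2$E_t)
  expect_gte(br2$E_b, 0)
  expect_gte(br2$E_t, 0)
  # energy invariant under rigid motion
  set.seed(8)
  vrot <- rotate_rigid(sk$vertices) + rep(1, 79) %o% rnorm(3, sd = 50)
  br3 <- total_energy(skeleton(vrot, l = sk$l, validate = FALSE), k, n_bp = 2686)
  expect_equal(br3$E, br2$E, tolerance = 1e-9)
})

test_that("incremental energy update matches full recomputation", {
  set.seed(17)
  k <- physical_constants()
  sk <- skeleton_from_bp(2686)
  br <- total_energy(sk, k, n_bp = 2686)

  # empty move returns the previous breakdown unchanged
  expect_identical(incremental_energy_update(br, sk, sk, integer(0), k, 2686), br)

  # single local moves
  cur <- sk
  cur_br <- br
  for (i in 1:25) {
    p <- propose_local_move(cur)
    nxt <- apply_proposal(cur, p)
    inc <- incremental_energy_update(cur_br, cur, nxt, p$moved, k, 2686)
    full <- total_energy(nxt, k, n_bp = 2686)
    expect_equal(inc$E, full$E, tolerance = 1e-9)
    expect_equal(inc$Wr, full$Wr, tolerance = 1e-9)
    cur <- nxt
    cur_br <- inc
  }

  # inconsistent moved set is rejected
  p <- propose_local_move(cur)
  nxt <- apply_proposal(cur, p)
  expect_error(incremental_energy_update(cur_br, cur, nxt, p$moved[1], k, 2686),
               "inconsistent")
})

test_that("incremental updates do not drift along a long move sequence", {
  set.seed(23)
  k <- physical_constants()
  sk <- skeleton_from_bp(600, min_bp = 25, max_bp = 35)  # small for speed
  cur <- sk
  cur_br <- total_energy(cur, k, n_bp = 600)
  for (i in 1:1000) {
    p <- propose_local_move(cur)
    if (is.null(p)) next
    nxt <- apply_proposal(cur, p)
    cur_br <- incremental_energy_update(cur_br, cur, nxt, p$moved, k, 600)
    cur <- nxt
  }
  full <- total_energy(cur, k, n_bp = 600)
  expect_equal(cur_br$E, full$E, tolerance = 1e-6)
  expect_equal(cur_br$Wr, full$Wr, tolerance = 1e-6)
})
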