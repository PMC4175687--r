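test_that("deterministic local move with zero parameters is the identity", {
  sk <- build_circular_skeleton(12, 1)
  p <- apply_local_move(sk, m = 4, vm_new = sk$vertices[4, ],
                        psi_left = 0, psi_right = 0)
  expect_lt(max(abs(p$new_pos - p$old_pos)), 1e-12)
})

test_that("local move displaces exactly three vertices within its bounds", {
  set.seed(31)
  sk <- skeleton_from_bp(2686)
  r <- 2 * 3.3
  for (i in 1:300) {
    p <- propose_local_move(sk, r = r)
    s2 <- apply_proposal(sk, p)
    diffs <- which(rowSums(s2$vertices != sk$vertices) > 0)
    expect_identical(sort(p$moved), diffs)
    expect_length(diffs, 3L)
    # mobile vertex within N_m, flanks within reach 2l
    expect_lte(sqrt(sum((p$new_pos[2, ] - p$old_pos[2, ])^2)), r + 1e-9)
    expect_lte(max(sqrt(rowSums((p$new_pos - p$old_pos)^2))), 2 * sk$l)
    # all other vertices bit-identical
    expect_identical(s2$vertices[-diffs, ], sk$vertices[-diffs, ])
    # closure and equal lengths preserved
    expect_lt(max(abs(brute_lengths(s2$vertices) - sk$l)) / sk$l, 1e-9)
  }
})

test_that("local move raw parameters stay in their admissible ranges", {
  set.seed(37)
  sk <- skeleton_from_bp(2686)
  for (i in 1:200) {
    p <- propose_local_move(sk)
    expect_lte(abs(p$params[["dd"]]), 6.6)
    expect_lte(abs(p$params[["dtheta"]]), pi)
    expect_lte(abs(p$params[["dphi"]]), pi)
    expect_lte(abs(p$params[["psi_left"]]), pi)
    expect_lte(abs(p$params[["psi_right"]]), pi)
  }
})

test_that("local move is geometrically reversible", {
  set.seed(41)
  sk <- skeleton_from_bp(2686)
  # reverse of the identity is the identity
  pid <- apply_local_move(sk, 5, sk$vertices[5, ], 0, 0)
  rid <- reverse_local_move(pid, apply_proposal(sk, pid))
  expect_lt(max(abs(rid$new_pos - rid$old_pos)), 1e-12)

  for (i in 1:200) {
    p <- propose_local_move(sk)
    s2 <- apply_proposal(sk, p)
    pr <- reverse_local_move(p, s2)
    s3 <- apply_proposal(s2, pr)
    expect_lt(max(abs(s3$vertices - sk$vertices)) / sk$l, 1e-9)
  }
})

test_that("crankshaft rotations preserve geometry and invert cleanly", {
  sk <- skeleton_from_bp(2686)
  # theta = 0 is the identity
  p0 <- standard_crankshaft(sk, m = 3, n = 10, theta = 0)
  expect_lt(max(abs(p0$new_pos - p0$old_pos)), 1e-12)
  # compose theta then -theta
  p1 <- standard_crankshaft(sk, m = 3, n = 10, theta = 1.3)
  s2 <- apply_proposal(sk, p1)
  p2 <- standard_crankshaft(s2, m = 3, n = 10, theta = -1.3)
  s3 <- apply_proposal(s2, p2)
  expect_lt(max(abs(s3$vertices - sk$vertices)), 1e-9)

  set.seed(43)
  for (i in 1:300) {
    p <- standard_crankshaft(sk)
    s2 <- apply_proposal(sk, p)
    expect_lt(max(abs(brute_lengths(s2$vertices) - sk$l)), 1e-9)
    # rotated arc is the shorter one
    expect_lte(length(p$moved), sk$s %/% 2)
  }
})

test_that("biased crankshaft angle range adapts toward half acceptance", {
  st <- angle_range_state(2.043)
  expect_equal(adapt_angle_range(st, 0.5)$theta_max, 2.043)
  expect_gt(adapt_angle_range(st, 1.0)$theta_max, 2.043)
  expect_lt(adapt_angle_range(st, 0.0)$theta_max, 2.043)
  # saturation at the pi cap and the lower clip
  up <- st
  for (i in 1:200) up <- adapt_angle_range(up, 1.0)
  expect_equal(up$theta_max, pi)
  dn <- st
  for (i in 1:500) dn <- adapt_angle_range(dn, 0.0)
  expect_gte(dn$theta_max, 1e-4)

  # proposals respect the current range
  set.seed(47)
  sk <- skeleton_from_bp(2686)
  narrow <- angle_range_state(0.01)
  for (i in 1:50) {
    p <- biased_crankshaft(sk, narrow)
    expect_lte(abs(p$theta), 0.01)
  }
})

test_that("reptation permutes segment vectors exactly", {
  sk <- skeleton_from_bp(2686)
  s <- sk$s
  set.seed(53)
  for (k in 1:300) {
    p <- reptation(sk)
    s2 <- apply_proposal(sk, p)
    expect_lt(max(abs(brute_lengths(s2$vertices) - sk$l)), 1e-9)
    # segment-vector multiset is preserved (permutation property)
    seg <- function(v) rbind(v[-1, ], v[1, ]) - v
    a <- round(sort(seg(sk$vertices)), 6)
    b <- round(sort(seg(s2$vertices)), 6)
    expect_identical(a, b)
    # moved sub-chain is rigidly translated by the gap-filling vector
    w <- sk$vertices[p$j %% s + 1, ] - sk$vertices[p$j, ]
    shift <- p$new_pos - sk$vertices[(p$moved - 2) %% s + 1, , drop = FALSE]
    expect_lt(max(abs(sweep(shift, 2, w))), 1e-9)
  }
  # sub-chain spanning the whole polygon is rejected
  expect_null(reptation(sk, i = 1, j = 1))
})
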