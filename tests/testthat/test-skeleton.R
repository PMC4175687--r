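test_that("segment-count rule matches exhaustive enumeration", {
  # pUC19: 34 bp/segment divides 2686 into 79 segments exactly
  cs <- choose_segment_count(2686, 25, 35)
  expect_identical(cs$s, 79L)
  expect_identical(cs$bp_per_segment, 34L)
  expect_identical(cs$residual_bp, 0L)

  # exact division
  expect_identical(choose_segment_count(3000, 29, 31)$s, 100L)

  # property: agrees with an independent enumeration over random inputs
  set.seed(42)
  for (k in 1:50) {
    n <- sample(500:100000, 1)
    mn <- sample(20:29, 1)
    mx <- sample(31:45, 1)
    cs <- choose_segment_count(n, mn, mx)
    cand <- do.call(rbind, lapply(mn:mx, function(i) {
      s_i <- floor(n / i + 0.5)
      data.frame(i = i, s = s_i, resid = abs(n - s_i * i))
    }))
    best <- cand[cand$resid == min(cand$resid), ]
    best <- best[order(abs(best$i - 30), best$i), ]
    expect_identical(cs$s, as.integer(best$s[1]))
    expect_identical(cs$bp_per_segment, as.integer(best$i[1]))
  }
})

test_that("segment-count rule rejects invalid inputs", {
  expect_error(choose_segment_count(2686, 31, 35), "min_bp")
  expect_error(choose_segment_count(2686, 25, 29), "min_bp")
  expect_error(choose_segment_count(60, 25, 35), "too small")
})

test_that("circular skeleton is a closed equal-chord polygon", {
  # hexagon: chord equals circumradius
  hex <- build_circular_skeleton(6, 1)
  expect_equal(sqrt(sum(hex$vertices[1, ]^2)), 1, tolerance = 1e-12)

  sk <- build_circular_skeleton(79, 34 * 3.3)
  lens <- brute_lengths(sk$vertices)
  expect_lt(max(abs(lens - sk$l)) / sk$l, 1e-9)
  # all vertices on a common circle in the z = 0 plane
  radii <- sqrt(rowSums(sk$vertices[, 1:2]^2))
  expect_lt(diff(range(radii)) / radii[1], 1e-12)
  expect_true(all(sk$vertices[, 3] == 0))
  # perimeter tracks the contour length within one segment
  expect_lt(abs(sk$s * sk$l - 2686 * 3.3), sk$l)
  # planar curve has zero writhe
  expect_equal(writhe_2b(sk)$Wr, 0, tolerance = 1e-12)

  expect_error(build_circular_skeleton(4, 1), "at least 5")
})

test_that("validation report matches brute-force measurement", {
  sk <- build_circular_skeleton(6, 1)
  expect_true(validate_skeleton(sk)$pass)

  bad <- sk
  bad$vertices[3, 1] <- bad$vertices[3, 1] + 0.1 * sk$l
  rep <- validate_skeleton(bad)
  expect_false(rep$pass)
  expect_true(rep$worst_segment %in% c(2L, 3L))

  # report agrees with an independent distance loop on random cases
  set.seed(7)
  for (k in 1:20) {
    v <- random_skeleton(sample(8:20, 1))$vertices
    i <- sample(nrow(v), 1)
    v[i, ] <- v[i, ] + rnorm(3, sd = 0.05)
    lens <- brute_lengths(v)
    l <- mean(lens)
    want <- max(abs(lens - l)) / l <= 1e-9
    expect_identical(validate_skeleton(skeleton(v, l = l, validate = FALSE))$pass,
                     want)
  }
})

test_that("skeleton_from_bp carries provenance attributes", {
  sk <- skeleton_from_bp(2686)
  expect_identical(attr(sk, "n_bp"), 2686L)
  expect_identical(attr(sk, "bp_per_segment"), 34L)
  expect_equal(sk$l, 34 * 3.3)
})
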