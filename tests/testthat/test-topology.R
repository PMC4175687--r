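test_that("projected segment intersection matches a sampling oracle", {
  # symmetric X crossing
  hit <- segments_cross(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  expect_equal(hit$point, c(0.5, 0.5), tolerance = 1e-12)
  # disjoint collinear
  expect_null(segments_cross(c(0, 0), c(1, 0), c(2, 0), c(3, 0)))
  # collinear overlap is flagged for resampling
  expect_error(segments_cross(c(0, 0), c(2, 0), c(1, 0), c(3, 0)), "degenerate")

  # random pairs vs dense point-sampling overlap test
  set.seed(11)
  for (k in 1:40) {
    a1 <- runif(2); a2 <- runif(2); b1 <- runif(2); b2 <- runif(2)
    hit <- segments_cross(a1, a2, b1, b2)
    t <- seq(1e-4, 1 - 1e-4, length.out = 120)
    pa <- outer(t, a2 - a1) + rep(1, 120) %o% a1
    pb <- outer(t, b2 - b1) + rep(1, 120) %o% b1
    dmin <- min(sqrt(outer(pa[, 1], pb[, 1], "-")^2 +
                       outer(pa[, 2], pb[, 2], "-")^2))
    if (!is.null(hit)) {
      expect_lt(dmin, 0.02)
    } else {
      expect_gt(dmin, 1e-4)
    }
  }
})

test_that("directional writhe: planarity, mirror antisymmetry, scaling", {
  poly <- build_circular_skeleton(12, 1)
  expect_identical(directional_writhe(poly), 0L)

  set.seed(3)
  tf <- make_fixture("trefoil", s = 30)
  dz <- directional_writhe(tf)
  expect_identical(abs(dz), 3L)  # minimal trefoil diagram: 3 equal-sign crossings
  mirror <- tf$vertices %*% diag(c(1, 1, -1))
  expect_identical(directional_writhe(mirror), -dz)
  expect_identical(directional_writhe(10 * tf$vertices), dz)
})

test_that("twist of a planar in-plane ribbon is zero and rotation-invariant", {
  ck <- build_circular_skeleton(16, 1)
  aux <- ck$vertices * 1.05  # radial in-plane offset
  expect_equal(ribbon_twist(ck, aux), 0, tolerance = 1e-12)

  set.seed(5)
  rc <- random_skeleton(14)
  tw0 <- ribbon_twist(rc)
  ang <- runif(1, 0, 2 * pi)
  vrot <- t(apply(rc$vertices, 1L,
                  function(p) plasmidmc:::rodrigues(p, c(0, 0, 1), ang)))
  arot <- t(apply(auxiliary_chain(rc), 1L,
                  function(p) plasmidmc:::rodrigues(p, c(0, 0, 1), ang)))
  expect_equal(ribbon_twist(skeleton(vrot, l = rc$l, validate = FALSE), arot),
               tw0, tolerance = 1e-9)
})

test_that("writhe via Lk - Tw agrees with the Gauss-integral oracle", {
  expect_equal(writhe_2b(build_circular_skeleton(10, 1))$Wr, 0,
               tolerance = 1e-12)
  set.seed(21)
  for (k in 1:30) {
    rc <- random_skeleton(sample(8:40, 1))
    rep <- writhe_2b(rc)
    expect_equal(rep$Wr, writhe_gauss(rc), tolerance = 1e-3)
    # Lk of the ribbon is an integer
    expect_lt(abs(rep$Lk - round(rep$Lk)), 1e-6)
    # mirror antisymmetry
    expect_equal(writhe_2b(rc$vertices %*% diag(c(1, 1, -1)))$Wr, -rep$Wr,
                 tolerance = 1e-9)
  }
})

test_that("Gauss oracle is rigid-motion invariant and self-consistent", {
  set.seed(9)
  rc <- random_skeleton(18)
  w0 <- writhe_gauss(rc)
  for (k in 1:5) {
    v <- rotate_rigid(rc$vertices)
    v <- v + rep(1, nrow(v)) %o% rnorm(3, sd = 5)
    expect_equal(writhe_gauss(v), w0, tolerance = 1e-9)
  }
})

test_that("Alexander test separates unknot, trefoil and figure-eight", {
  set.seed(2)
  ck <- make_fixture("circle", s = 20)
  kc <- is_unknotted(ck)
  expect_true(kc$is_unknotted)
  expect_equal(unname(kc$alexander_values[1]), 1, tolerance = 1e-6)

  tf <- make_fixture("trefoil", s = 30)
  kt <- is_unknotted(tf)
  expect_false(kt$is_unknotted)
  expect_equal(unname(kt$alexander_values[1]), 3, tolerance = 1e-6)

  f8 <- make_fixture("figure-eight", s = 40)
  k8 <- is_unknotted(f8)
  expect_false(k8$is_unknotted)
  expect_equal(unname(k8$alexander_values[1]), 5, tolerance = 1e-6)
})

test_that("knot verdicts are invariant under rigid rotation", {
  set.seed(13)
  tf <- make_fixture("trefoil", s = 30)
  ck <- make_fixture("perturbed-circle", s = 20, seed = 4)
  for (k in 1:20) {
    expect_false(is_unknotted(rotate_rigid(tf$vertices))$is_unknotted)
    expect_true(is_unknotted(rotate_rigid(ck$vertices))$is_unknotted)
  }
})
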