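test_that("chirality vectors match the naive double-loop oracle", {
  conf <- fixture_random_conf(5L, seed = 11)
  g <- build_graph(conf)
  cv <- chirality_vectors(g)
  # naive per-term oracle over the printed double sum
  for (e in seq_len(nrow(g$edges))) {
    i <- g$edges[e, 1L]; j <- g$edges[e, 2L]
    acc <- c(0, 0, 0)
    d_ij <- g$directions[e, ]
    for (k in setdiff(g$neighbors[[i]], j)) {
      ek <- which(g$edges[, 1L] == i & g$edges[, 2L] == k)
      d_ik <- g$directions[ek, ]
      acc <- acc + c(d_ij[2] * d_ik[3] - d_ij[3] * d_ik[2],
                     d_ij[3] * d_ik[1] - d_ij[1] * d_ik[3],
                     d_ij[1] * d_ik[2] - d_ij[2] * d_ik[1])
    }
    expect_lt(max(abs(cv$c[e, ] - acc)), 1e-12)
  }
})

test_that("collinear molecules give degenerate chirality vectors", {
  conf <- conformation(rep(6L, 4L), cbind(1:4 * 1.2, 0, 0))
  g <- build_graph(conf)
  cv <- chirality_vectors(g)
  expect_true(all(cv$degenerate_mask))
  expect_lt(max(abs(cv$c)), 1e-12)
  tors <- torsion_angles(cv, g)
  expect_true(all(tors$psi == 0))
  expect_false(any(tors$valid))
})

test_that("chirality vectors rotate with the molecule", {
  conf <- fixture_random_conf(7L, seed = 2)
  g <- build_graph(conf)
  cv <- chirality_vectors(g)
  rot <- random_rotation(seed = 5)
  g2 <- build_graph(transform_conformation(conf, rot, c(1, -2, 0.5)))
  cv2 <- chirality_vectors(g2)
  expect_lt(max(abs(cv2$c - cv$c %*% t(rot))), 1e-9)
})

test_that("torsion angles are symmetric, SE(3)-invariant, reflection-odd", {
  for (seed in c(3, 8, 21)) {
    conf <- fixture_random_conf(8L, seed = seed)
    g <- build_graph(conf)
    tors <- torsion_angles(chirality_vectors(g), g)
    expect_true(all(abs(tors$psi) <= pi / 2))
    expect_lt(max(abs(tors$psi - tors$psi[g$rev_index])), 1e-12)
    # rigid motion
    rot <- random_rotation(seed = seed + 100L)
    g2 <- build_graph(transform_conformation(conf, rot, rnorm(3)))
    tors2 <- torsion_angles(chirality_vectors(g2), g2)
    expect_lt(max(abs(tors2$psi - tors$psi)), 1e-9)
    # reflection
    gr <- build_graph(reflect_conformation(conf))
    torsr <- torsion_angles(chirality_vectors(gr), gr)
    expect_lt(max(abs(torsr$psi[torsr$valid] + tors$psi[tors$valid])), 1e-9)
  }
})

test_that("planar molecules have zero torsion on all edges", {
  withr::with_seed(4, {
    pos <- cbind(matrix(runif(12, -2, 2), 6L, 2L), 0)
  })
  conf <- conformation(rep(6L, 6L), pos)
  g <- build_graph(conf)
  tors <- torsion_angles(chirality_vectors(g), g)
  expect_lt(max(abs(tors$psi)), 1e-9)
})

test_that("circular harmonics follow the printed sin/cos layout", {
  ch0 <- circular_harmonics(0, Omega = 3L)
  expect_equal(ncol(ch0), 2L * (2L * 3L + 1L))
  expect_true(all(ch0[, 1:7] == 0))   # sin block
  expect_true(all(ch0[, 8:14] == 1))  # cos block
  # direct scalar oracle at psi = pi/4, Omega = 2
  ch <- circular_harmonics(pi / 4, Omega = 2L)
  omega <- -2:2
  expect_equal(drop(ch), c(sin(omega * pi / 4), cos(omega * pi / 4)))
  expect_true(all(abs(ch) <= 1))
  # reflection negates the sin block only
  psi <- runif(10, -pi / 2, pi / 2)
  a <- circular_harmonics(psi, 4L)
  b <- circular_harmonics(-psi, 4L)
  expect_equal(b[, 1:9], -a[, 1:9])
  expect_equal(b[, 10:18], a[, 10:18])
  expect_error(circular_harmonics(0.1, Omega = 0L), "Omega")
})

test_that("radial basis peaks at centers and matches the closed form", {
  r <- radial_embedding(2.5, n_basis = 11L, r_max = 5)
  centers <- seq(0, 5, length.out = 11L)
  expect_equal(r[1, which(centers == 2.5)], 1)
  # monotone decay away from a center
  expect_true(all(diff(r[1, centers >= 2.5]) <= 0))
  expect_true(all(diff(r[1, centers <= 2.5]) >= 0))
  lengths <- runif(20, 0.5, 4.5)
  rb <- radial_embedding(lengths, 8L, 5)
  cc <- seq(0, 5, length.out = 8L)
  w <- cc[2] - cc[1]
  oracle <- exp(-0.5 * ((outer(lengths, cc, `-`)) / w)^2)
  expect_equal(rb, oracle)
  expect_error(radial_embedding(1, 8L, -1), "r_max")
})

test_that("encoder output is rigid-motion invariant", {
  conf <- fixture_random_conf(9L, seed = 13)
  enc <- init_se3_encoder(hidden_dim = 12L, Omega = 2L, n_basis = 6L,
                          seed = 3L)
  g <- build_graph(conf)
  f1 <- se3_encode(conf, g, enc)
  rot <- random_rotation(seed = 77)
  conf2 <- transform_conformation(conf, rot, c(0.4, -3, 1))
  f2 <- se3_encode(conf2, build_graph(conf2), enc)
  expect_lt(max(abs(f1$node - f2$node)), 1e-6)
  expect_lt(max(abs(f1$edge - f2$edge)), 1e-6)
})

test_that("torsion ablation makes the encoder reflection-blind", {
  mol <- make_chiral_dataset(1, seed = 5)[[1]]
  conf <- mol$conformation
  mirror <- reflect_conformation(conf)
  enc_off <- init_se3_encoder(hidden_dim = 12L, use_torsion = FALSE,
                              seed = 3L)
  f1 <- se3_encode(conf, build_graph(conf), enc_off)
  f2 <- se3_encode(mirror, build_graph(mirror), enc_off)
  expect_identical(f1$node, f2$node)
  expect_identical(f1$edge, f2$edge)
  enc_on <- init_se3_encoder(hidden_dim = 12L, use_torsion = TRUE, seed = 3L)
  g1 <- se3_encode(conf, build_graph(conf), enc_on)
  g2 <- se3_encode(mirror, build_graph(mirror), enc_on)
  expect_gt(max(abs(g1$edge - g2$edge)), 1e-4)
})

test_that("unknown elements are reported with the supported list", {
  conf <- conformation(c(6L, 92L), rbind(c(0, 0, 0), c(1.4, 0, 0)))
  enc <- init_se3_encoder(hidden_dim = 8L)
  g <- build_graph(conf, min_neighbors = 1L)
  expect_error(se3_encode(conf, g, enc), "92.*supported atomic numbers")
})
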