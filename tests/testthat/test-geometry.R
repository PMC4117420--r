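# Continuous-space hexagonal-lattice arithmetic and the P6 pose geometry.

test_that("hexagonal lattice vectors reproduce the published film lattices", {
  # (a, published b components) for the HFBI/HFBII structures
  cases <- rbind(c(54.000, -27.000, 46.765),
                 c(55.000, -27.500, 47.631),
                 c(64.537, -32.269, 55.891),
                 c(54.723, -27.362, 47.392))
  for (k in seq_len(nrow(cases))) {
    v <- hexLatticeVectors(cases[k, 1])
    expect_equal(unname(v["a", ]), c(cases[k, 1], 0, 0))
    expect_equal(round(unname(v["b", ]), 3), c(cases[k, 2], cases[k, 3], 0))
  }
  expect_equal(unname(hexLatticeVectors(2)["b", ]), c(-1, sqrt(3), 0))
  expect_error(hexLatticeVectors(-5), "positive")
  expect_error(hexLattice(0), "must be > 0")
})

test_that("lattice vectors have equal norms at 120 degrees for random a", {
  set.seed(11)
  for (a in runif(1000, 0.1, 200)) {
    v <- hexLatticeVectors(a)
    expect_lt(abs(sqrt(sum(v["a", ]^2)) - a), 1e-9)
    expect_lt(abs(sqrt(sum(v["b", ]^2)) - a), 1e-9)
    cosang <- sum(v["a", ] * v["b", ]) / a^2
    expect_lt(abs(cosang - cos(2 * pi / 3)), 1e-9)
  }
})

test_that("superlattice lengths bracket the observed film lattice constant", {
  expect_equal(round(superlatticeLength(1, 1, d = 20), 2), 34.64)
  expect_equal(round(superlatticeLength(1, 1, d = 20)), 35)
  expect_equal(round(superlatticeLength(2, 1, d = 20), 2), 52.92)
  expect_equal(round(superlatticeLength(2, 1, d = 20)), 53)
  expect_equal(superlatticeLength(1, 0, d = 20), 20)
  expect_error(superlatticeLength(0, 0), "invalid")
  expect_error(superlatticeLength(1, 1, d = 0), "> 0")
})

# independent oracle: count residue classes of Z^2 modulo the superlattice
# spanned by (m, n) and its 60-degree rotation (-n, m+n), using exact
# integer arithmetic (adjugate over the numerically computed determinant)
cosetCount <- function(m, n) {
  A <- cbind(c(m, n), c(-n, m + n))
  D <- round(abs(det(A)))
  keys <- character(0)
  rng <- 0:(2L * D)
  for (i in rng) for (j in rng) {
    keys <- c(keys, paste(((m + n) * i + n * j) %% D,
                          (-n * i + m * j) %% D, sep = ","))
  }
  length(unique(keys))
}

test_that("sites per supercell matches a coset-counting oracle", {
  expect_identical(sitesPerSupercell(2, 1), 7L)   # seven-site unit cell
  expect_identical(sitesPerSupercell(1, 0), 1L)
  expect_identical(sitesPerSupercell(1, 1), 3L)
  for (case in list(c(1, 1), c(2, 1), c(3, 1), c(2, 2))) {
    expect_identical(sitesPerSupercell(case[1], case[2]),
                     as.integer(cosetCount(case[1], case[2])))
  }
  expect_error(sitesPerSupercell(0, 0), "invalid")
})

test_that("squared superlattice length is an integer multiple of d^2", {
  for (m in -10:10) for (n in -10:10) {
    if (m == 0 && n == 0) next
    q <- superlatticeLength(m, n, d = 1)^2
    expect_lt(abs(q - round(q)), 1e-9)
    expect_equal(round(q), sitesPerSupercell(m, n))
  }
})

test_that("the minimal box commensurate with both crystals is 14 x 14", {
  expect_identical(commensurateCell(), c(14L, 14L))
  # component minima: sqrt(7) vacancy lattice and 2x2 P3 superlattice
  expect_identical(hydrofilm:::.minPeriod(cbind(c(2, 1), c(-1, 3))), 7L)
  expect_identical(hydrofilm:::.minPeriod(cbind(c(2, 0), c(0, 2))), 2L)
})

test_that("generated hexamer poses have exact P6 symmetry", {
  pp <- p6Params(rTrimer = 20, dTrimers = 30, psi = 0, euler = c(0, 0, 0))
  poses <- p6GeneratePoses(pp)
  expect_equal(nrow(poses), 6L)
  # centroid of the six poses is the midpoint of the trimer centres (origin)
  expect_lt(max(abs(colMeans(cbind(poses$x, poses$y)))), 1e-9)
  # 3-fold symmetry of trimer 1 about its centre
  t1 <- poses[poses$trimer == 1, ]
  c1 <- c(mean(t1$x), mean(t1$y))
  th <- 2 * pi / 3
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- sweep(as.matrix(t1[, c("x", "y")]), 2, c1) %*% t(R)
  rot <- sweep(rot, 2, c1, "+")
  for (k in 1:3) {
    dists <- sqrt((t1$x - rot[k, 1])^2 + (t1$y - rot[k, 2])^2)
    expect_lt(min(dists), 1e-9)
  }
  # 2-fold symmetry about the midpoint
  t2 <- poses[poses$trimer == 2, ]
  expect_equal(sort(round(-t1$x, 9)), sort(round(t2$x, 9)))
  expect_equal(sort(round(-t1$y, 9)), sort(round(t2$y, 9)))
})

test_that("pose generation and parameter extraction round-trip exactly", {
  circdist <- function(a, b, period = 2 * pi)
    abs(((a - b + period / 2) %% period) - period / 2)
  # d = 2r with psi = 0 is avoided: it would put two proteins at the same
  # point (a genuinely degenerate hexamer)
  grid <- expand.grid(r = c(12, 20), d = c(25, 41),
                      psi = c(0, 0.3, 1.9), e1 = c(0, 0.7, 4.4))
  for (k in seq_len(nrow(grid))) {
    pp <- p6Params(rTrimer = grid$r[k], dTrimers = grid$d[k],
                   psi = grid$psi[k] %% (2 * pi / 3),
                   euler = c(grid$e1[k] %% (2 * pi), 0, 0))
    fit <- p6ExtractParams(p6GeneratePoses(pp))
    expect_lt(fit$deviation, 1e-9)
    expect_lt(abs(fit$params@rTrimer - pp@rTrimer), 1e-9)
    expect_lt(abs(fit$params@dTrimers - pp@dTrimers), 1e-9)
    expect_lt(circdist(fit$params@psi, pp@psi, 2 * pi / 3), 1e-9)
    expect_lt(circdist(fit$params@euler[1], pp@euler[1]), 1e-9)
    # regenerating from the fitted parameters reproduces the poses
    re <- p6GeneratePoses(fit$params)
    expect_equal(re, p6GeneratePoses(pp), tolerance = 1e-9)
  }
})

test_that("fit deviation is bounded by the perturbation magnitude", {
  pp <- p6Params(rTrimer = 20, dTrimers = 31, psi = 0.4, euler = c(0.7, 0, 0))
  poses <- p6GeneratePoses(pp)
  set.seed(5)
  for (rep in 1:20) {
    ang <- runif(6, 0, 2 * pi)
    pert <- poses
    pert$x <- pert$x + 0.5 * cos(ang)
    pert$y <- pert$y + 0.5 * sin(ang)
    expect_lte(p6ExtractParams(pert)$deviation, 0.5)
  }
})

test_that("fit deviation is invariant under global rigid motion", {
  pp <- p6Params(rTrimer = 18, dTrimers = 28, psi = 0.9, euler = c(2.2, 0, 0))
  poses <- p6GeneratePoses(pp)
  set.seed(6)
  poses$x <- poses$x + rnorm(6, sd = 0.3)
  poses$y <- poses$y + rnorm(6, sd = 0.3)
  d0 <- p6ExtractParams(poses)$deviation
  th <- 1.2
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  P <- as.matrix(poses[, c("x", "y")]) %*% t(R)
  moved <- poses
  moved$x <- P[, 1] + 17; moved$y <- P[, 2] - 4
  moved$theta <- (poses$theta + th) %% (2 * pi)
  expect_lt(abs(p6ExtractParams(moved)$deviation - d0), 1e-9)
})

test_that("pose extraction rejects malformed input", {
  pp <- p6Params(rTrimer = 20, dTrimers = 30)
  poses <- p6GeneratePoses(pp)
  expect_error(p6ExtractParams(poses[1:5, ]), "6 rows")
  expect_error(p6ExtractParams(poses, rep(1L, 6)), "exactly 3")
  dup <- poses
  dup$x <- rep(1, 6); dup$y <- rep(2, 6)
  expect_error(p6ExtractParams(dup), "degenerate|coincident")
  expect_error(p6Params(rTrimer = -1, dTrimers = 30), "rTrimer")
  expect_error(p6Params(rTrimer = 20, dTrimers = 30, euler = c(0, 0.1, 0)),
               "out-of-plane")
})
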