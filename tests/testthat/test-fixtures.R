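# Synthetic fixture generators and plain-text IO.

test_that("random gases are valid, reproducible and density-targeted", {
  expect_identical(nOccupied(makeRandomConfig(10, 10, 0, seed = 1, .tabBoth)),
                   0L)
  for (k in 1:20) {
    cfg <- makeRandomConfig(14, 14, 0.4, seed = k, .tabBoth)
    cen <- bondCensus(cfg, .tabBoth)
    expect_identical(unname(cen["n_forbidden"]), 0L)
    expect_true(is.finite(configEnergy(cfg, .tabBoth, .mpDefault)))
    expect_identical(cfg@metadata$achieved_density, occupancy(cfg))
  }
  a <- makeRandomConfig(12, 12, 0.5, seed = 42, .tabBoth)
  b <- makeRandomConfig(12, 12, 0.5, seed = 42, .tabBoth)
  expect_identical(spins(a), spins(b))
  expect_false(identical(spins(a),
                         spins(makeRandomConfig(12, 12, 0.5, seed = 43,
                                                .tabBoth))))
  # moderate densities are reachable exactly
  expect_equal(occupancy(makeRandomConfig(20, 20, 0.3, seed = 7, .tabBoth)),
               0.3)
})

test_that("two-domain fixtures hold separate mismatched crystals", {
  td <- makeTwoDomainConfig(4, 4, sublatticeA = 0L, sublatticeB = 1L, gap = 2L)
  expect_true(is.finite(configEnergy(td, .tabP6, .mpDefault)))
  lab <- labelClusters(td, .tabP6)
  expect_gte(length(clusterSizes(lab)), 2L)
  expect_lt(largestClusterSize(lab), nOccupied(td))
  expect_error(makeTwoDomainConfig(4, 4, 2L, 2L), "differ")
  expect_error(makeTwoDomainConfig(3, 4), "even")
  expect_error(makeTwoDomainConfig(4, 4, gap = 0L), "gap")
})

# interior representative sites of the two domains, as (row, col) matrix
# indices into the label matrix
.domainReps <- function(td) {
  W <- latticeWidth(td)
  sp0 <- spins(td)
  siteA <- which(sp0[1:5, ] >= 0L, arr.ind = TRUE)[1, ]
  siteB <- which(sp0[(W %/% 2 + 1):(W %/% 2 + 5), ] >= 0L, arr.ind = TRUE)[1, ]
  siteB[1] <- siteB[1] + W %/% 2
  list(a = siteA, b = siteB)
}

test_that("a P6-only quench cannot merge mismatched domains", {
  # sublattice pair (0, 2) is bridgeable, but only through a P3 dock: with
  # the P3 interaction disabled every boundary adsorption is forbidden
  td <- makeTwoDomainConfig(4, 2, 0L, 2L, gap = 1L)
  de <- vapply(enumerateMoves(td, .tabP6, includeTrimer = FALSE),
               function(m) deltaEnergy(td, .tabP6, .mpDefault, m), numeric(1))
  expect_gt(min(de), 0)                     # frozen: no move lowers energy
  q <- quench(td, .tabP6, .mpDefault, seed = 5)
  lab <- clusterLabels(labelClusters(q, .tabP6))
  reps <- .domainReps(td)
  expect_false(lab[reps$a[1], reps$a[2]] == lab[reps$b[1], reps$b[2]])
})

test_that("P3 docking glues mismatched domains across a tight boundary", {
  merged <- 0L
  for (seed in 1:5) {
    td <- makeTwoDomainConfig(4, 2, 0L, 2L, gap = 1L)
    run <- runSimulation(td, .tabBoth, .mpDefault, mcParams(30, seed = seed))
    fin <- run$final
    lab <- clusterLabels(labelClusters(fin, .tabBoth))
    reps <- .domainReps(td)
    if (lab[reps$a[1], reps$a[2]] == lab[reps$b[1], reps$b[2]] &&
        lab[reps$a[1], reps$a[2]] > 0L) {
      merged <- merged + 1L
      # the glue is the metastable interaction: P3 bonds appeared
      expect_gt(unname(bondCensus(fin, .tabBoth)["n_p3"]), 0L)
    }
  }
  expect_gte(merged, 1L)
})

test_that("defected tilings thin the crystal as requested", {
  base <- buildP6Tiling(4, 4)
  expect_identical(spins(makeDefectedTiling("p6", 4, 0, seed = 1)),
                   spins(base))
  set.seed(1)
  occs <- vapply(1:20, function(sd)
    nOccupied(makeDefectedTiling("p6", 4, 0.5, seed = sd)), integer(1))
  n0 <- nOccupied(base)
  expect_lt(abs(mean(occs) / n0 - 0.5), 0.05)   # binomial thinning
  # heavy dilution destroys percolation (site dilution far below threshold)
  for (sd in 1:20) {
    cfg <- makeDefectedTiling("p6", 4, 0.7, seed = sd)
    expect_false(detectPercolation(labelClusters(cfg, .tabP6)))
  }
  expect_error(makeDefectedTiling("p6", 4, 1, seed = 1), "defectFraction")
})

test_that("snapshot files round-trip bit-exactly", {
  cfgs <- list(buildP6Tiling(1, 1), buildP3Tiling(3, 2, phase = 1L),
               makeRandomConfig(9, 5, 0.4, seed = 3, .tabBoth))
  for (cfg in cfgs) {
    f <- tempfile(fileext = ".tsv")
    writeSnapshot(cfg, f)
    back <- readSnapshot(f)
    expect_identical(spins(back), spins(cfg))
    unlink(f)
  }
  lines <- readLines(writeSnapshot(buildP3Tiling(1, 1), f2 <- tempfile()))
  expect_identical(lines[1:2], c("#width 2", "#height 2"))
  expect_identical(length(lines), 4L)
  unlink(f2)
})

test_that("time-series files round-trip through CSV", {
  run <- runSimulation(emptyLattice(14, 14), .tabBoth, .mpDefault,
                       mcParams(5, seed = 2))
  f <- tempfile(fileext = ".csv")
  writeTimeSeries(run$series, f)
  back <- readTimeSeries(f)
  expect_equal(back, run$series)
  expect_identical(readLines(f)[1],
                   "sweep,n_occupied,largest_cluster,energy,n_trimer,n_p6,n_p3,percolated")
  unlink(f)
})
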