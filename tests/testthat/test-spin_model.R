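# Interaction table structure, energies and incremental evaluation.

test_that("the interaction table has the constructed closed-form structure", {
  cls <- tableClasses(.tabBoth)
  # derived by hand from the canonical trimer placement and the two
  # reference tilings (frozen oracle): orientation s trimer-bonds s+2 along
  # direction s and s+4 along s+1; P6 docks (s+2,s,s+3), (s+3,s,s+1),
  # (s+5,s,s+5); P3 docks (s+3,s,s+2), (s+4,s,s+4) -- all mod 6.
  expected <- array(0L, dim = c(6, 6, 6))
  for (s in 0:5) {
    put <- function(d, sj, code)
      expected[(d %% 6) + 1, s + 1, (sj %% 6) + 1] <<- code
    put(s, s + 2, 1L); put(s + 1, s + 4, 1L)
    put(s + 2, s + 3, 2L); put(s + 3, s + 1, 2L); put(s + 5, s + 5, 2L)
    put(s + 3, s + 2, 3L); put(s + 4, s + 4, 3L)
  }
  expect_identical(cls, expected)
  expect_identical(sum(cls == 1L), 12L)   # 6 orientations x 2 partner dirs
  expect_identical(sum(cls == 2L), 18L)
  expect_identical(sum(cls == 3L), 12L)
})

test_that("the table is reciprocal over all 216 triples", {
  for (tab in list(.tabBoth, .tabP6)) {
    cls <- tableClasses(tab)
    for (d in 0:5) for (si in 0:5) for (sj in 0:5)
      expect_identical(cls[d + 1, si + 1, sj + 1],
                       cls[((d + 3) %% 6) + 1, sj + 1, si + 1])
  }
})

test_that("disabling P3 turns its dock entries into forbidden ones", {
  clsB <- tableClasses(.tabBoth)
  cls6 <- tableClasses(.tabP6)
  expect_identical(sum(cls6 == 3L), 0L)
  expect_false(p3Enabled(.tabP6))
  # former P3 triples are forbidden; everything else is unchanged
  expect_identical(cls6[clsB == 3L], rep(0L, 12L))
  expect_identical(cls6[clsB != 3L], clsB[clsB != 3L])
})

test_that("invalid tables are rejected by the validity method", {
  cls <- tableClasses(.tabBoth)
  broken <- cls
  broken[1, 1, 3] <- 0L   # delete the (d0, s0, s2) trimer entry one-sidedly
  expect_error(interactionTable(broken), "reciprocity|trimer")
  expect_error(interactionTable(cls, p3Enabled = FALSE), "P3")
})

test_that("configuration energies match hand counts", {
  mp <- .mpDefault
  expect_identical(configEnergy(emptyLattice(8, 8), .tabBoth, mp), 0)
  sp <- matrix(-1L, 8, 8)
  sp[3, 3] <- 0L
  expect_identical(configEnergy(FilmLattice(sp), .tabBoth, mp), -10)
  # canonical trimer: 3 trimer bonds x 5 + 3 sites x 10 = 45
  sp[4, 3] <- 2L; sp[3, 4] <- 4L
  tri <- FilmLattice(sp)
  expect_identical(configEnergy(tri, .tabBoth, mp), -45)
  cen <- bondCensus(tri, .tabBoth)
  expect_identical(unname(cen[c("n_trimer", "n_p6", "n_p3", "n_forbidden",
                                "n_occupied")]),
                   c(3L, 0L, 0L, 0L, 3L))
  # an adjacent incompatible pair is forbidden -> infinite energy
  sp2 <- matrix(-1L, 8, 8)
  sp2[3, 3] <- 0L; sp2[4, 3] <- 0L
  expect_identical(configEnergy(FilmLattice(sp2), .tabBoth, mp), Inf)
  expect_identical(unname(bondCensus(FilmLattice(sp2), .tabBoth)["n_forbidden"]),
                   1L)
})

test_that("bond census of an empty lattice is all zeros", {
  cen <- bondCensus(emptyLattice(5, 5), .tabBoth)
  expect_identical(unname(cen), rep(0L, 5L))
})

test_that("incremental delta energy equals full recomputation", {
  mp <- .mpDefault
  set.seed(101)
  checked <- 0L
  for (k in 1:60) {
    cfg <- makeRandomConfig(10, 10, runif(1, 0.1, 0.6), seed = 1000 + k,
                            .tabBoth)
    sp <- spins(cfg)
    e0 <- configEnergy(cfg, .tabBoth, mp)
    for (r in 1:20) {
      i <- sample(0:9, 1); j <- sample(0:9, 1)
      occ <- sp[i + 1, j + 1] >= 0L
      mv <- if (!occ) {
        moveAdsorb(i, j, sample(0:5, 1))
      } else if (runif(1) < 0.3) {
        moveDesorb(i, j)
      } else {
        moveHop(i, j, sample(c(NA, 0:5), 1),
                sample(c(-1L, 0L, 1L), 1))
      }
      if (mv$type == "hop" && is.na(mv$dir) && mv$rot == 0L) next
      de <- deltaEnergy(cfg, .tabBoth, mp, mv)
      after <- tryCatch(applyMove(cfg, .tabBoth, mv), error = function(e) NULL)
      if (is.null(after)) {      # geometrically impossible => rejected
        expect_identical(de, Inf)
        next
      }
      expect_lt(abs(min(de, 1e18) - min(configEnergy(after, .tabBoth, mp) - e0,
                                        1e18)), 1e-9)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 800L)
})

test_that("delta energy covers rigid trimer moves exactly", {
  mp <- .mpDefault
  # a sparse config with several complete trimers
  cfg <- buildP3Tiling(5, 5)
  sp <- spins(cfg)
  sp[, 7:10] <- -1L           # open space so trimers can move
  cfg <- FilmLattice(sp)
  e0 <- configEnergy(cfg, .tabBoth, mp)
  moves <- enumerateMoves(cfg, .tabBoth, includeTrimer = TRUE)
  moves <- Filter(function(m) m$type == "trimer", moves)
  expect_gt(length(moves), 100L)
  for (mv in moves) {
    de <- deltaEnergy(cfg, .tabBoth, mp, mv)
    after <- tryCatch(applyMove(cfg, .tabBoth, mv), error = function(e) NULL)
    if (is.null(after)) {
      expect_identical(de, Inf)
    } else {
      full <- configEnergy(after, .tabBoth, mp) - e0
      expect_lt(abs(min(de, 1e18) - min(full, 1e18)), 1e-9)
    }
  }
})

test_that("removing one protein from an isolated trimer costs 25 kT", {
  sp <- matrix(-1L, 8, 8)
  sp[3, 3] <- 0L; sp[4, 3] <- 2L; sp[3, 4] <- 4L
  cfg <- FilmLattice(sp)
  expect_identical(deltaEnergy(cfg, .tabBoth, .mpDefault, moveDesorb(2, 2)),
                   2 * 5 + 10)
  expect_identical(deltaEnergy(emptyLattice(6, 6), .tabBoth, .mpDefault,
                               moveAdsorb(1, 1, 4L)), -10)
})

test_that("malformed moves raise errors", {
  cfg <- buildP3Tiling(3, 3)
  mp <- .mpDefault
  expect_error(deltaEnergy(cfg, .tabBoth, mp, moveAdsorb(0, 0, 3L)), "occupied")
  expect_error(deltaEnergy(cfg, .tabBoth, mp, moveDesorb(1, 1)), "vacant")
  expect_error(deltaEnergy(cfg, .tabBoth, mp, moveAdsorb(1, 1, 9L)), "0..5")
  expect_error(deltaEnergy(cfg, .tabBoth, mp, moveHop(0, 0, NA, 0L)), "null")
  expect_error(deltaEnergy(cfg, .tabBoth, mp, moveAdsorb(99, 0, 1L)), "outside")
  # a protein not in a complete trimer cannot make a trimer move
  sp <- matrix(-1L, 8, 8); sp[3, 3] <- 0L
  expect_error(deltaEnergy(FilmLattice(sp), .tabBoth, mp,
                           moveTrimer(2, 2, dir = 0L)), "complete trimer")
})

test_that("the P6 crystal is a strict local minimum under all moves", {
  p6 <- buildP6Tiling(1, 1)
  for (tab in list(.tabP6, .tabBoth)) {
    de <- vapply(enumerateMoves(p6, tab, includeTrimer = TRUE),
                 function(m) deltaEnergy(p6, tab, .mpDefault, m), numeric(1))
    expect_gt(min(de), 0)
  }
})

test_that("the P3 crystal is metastable under all single-protein moves", {
  p3 <- buildP3Tiling(7, 7)   # 14 x 14 sites
  de <- vapply(enumerateMoves(p3, .tabBoth, includeTrimer = FALSE),
               function(m) deltaEnergy(p3, .tabBoth, .mpDefault, m),
               numeric(1))
  expect_gt(min(de), 0)
})

test_that("no finite configuration has a site with more than 2 trimer bonds", {
  cls <- tableClasses(.tabBoth)
  for (k in 1:30) {
    cfg <- makeRandomConfig(12, 12, 0.5, seed = 300 + k, .tabBoth)
    sp <- spins(cfg)
    for (j in 0:11) for (i in 0:11) {
      s <- sp[i + 1, j + 1]
      if (s < 0L) next
      nb <- 0L
      for (d in 0:5) {
        sn <- sp[((i + DXo[d + 1]) %% 12) + 1, ((j + DYo[d + 1]) %% 12) + 1]
        if (sn >= 0L && cls[d + 1, s + 1, sn + 1] == 1L) nb <- nb + 1L
      }
      expect_lte(nb, 2L)
    }
  }
})
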