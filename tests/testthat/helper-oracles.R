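# Shared fixtures and independent oracles for the test suite.

# cached tables / params (construction is cheap but repeated a lot)
.tabP6 <- buildInteractionTable(p3Enabled = FALSE)
.tabBoth <- buildInteractionTable(p3Enabled = TRUE)
.mpDefault <- modelParams()

DXo <- c(1L, 0L, -1L, -1L, 0L, 1L)
DYo <- c(0L, 1L, 1L, 0L, -1L, -1L)

# Breadth-first-search cluster oracle, independent of the union-find
# implementation: labels connected components over attractive bonds and
# detects percolation by unwrapped-coordinate conflicts.
bfsClusters <- function(cfg, table) {
  sp <- spins(cfg)
  W <- nrow(sp); H <- ncol(sp)
  cls <- tableClasses(table)
  lab <- matrix(0L, W, H)
  sizes <- integer(0)
  wraps <- logical(0)
  nl <- 0L
  for (site in seq_along(sp)) {
    if (sp[site] < 0L || lab[site] > 0L) next
    nl <- nl + 1L
    wrap <- FALSE
    size <- 0L
    # queue of (site index, unwrapped x, unwrapped y)
    ux <- uy <- rep(NA_real_, length(sp))
    queue <- site; ux[site] <- 0; uy[site] <- 0
    lab[site] <- nl
    while (length(queue)) {
      a <- queue[1L]; queue <- queue[-1L]
      size <- size + 1L
      ai <- (a - 1L) %% W; aj <- (a - 1L) %/% W
      for (d in 0:5) {
        bi <- (ai + DXo[d + 1L]) %% W; bj <- (aj + DYo[d + 1L]) %% H
        b <- bi + W * bj + 1L
        if (sp[b] < 0L) next
        if (cls[d + 1L, sp[a] + 1L, sp[b] + 1L] == 0L) next
        nx <- ux[a] + DXo[d + 1L]; ny <- uy[a] + DYo[d + 1L]
        if (is.na(ux[b])) {
          ux[b] <- nx; uy[b] <- ny
          lab[b] <- nl
          queue <- c(queue, b)
        } else if (ux[b] != nx || uy[b] != ny) {
          wrap <- TRUE
        }
      }
    }
    sizes <- c(sizes, size)
    wraps <- c(wraps, wrap)
  }
  list(labels = lab, sizes = sizes, wraps = wraps)
}

# canonical form of a labelling: for each cluster, the sorted site indices,
# sorted lexicographically -- partition comparison independent of label ids
canonicalPartition <- function(labels) {
  occ <- which(labels > 0L)
  unname(sort(vapply(split(occ, labels[occ]),
                     function(s) paste(sort(s), collapse = ","), "")))
}

# rotate a configuration by 120 degrees about the centroid of the three
# sites given as a 3 x 2 matrix of axial coordinates (works in tripled
# coordinates so the centroid need not be a lattice point); spins advance
# by 2. Box must be square for the rotation to close on the torus.
rotate120About <- function(cfg, triSites) {
  sp <- spins(cfg)
  W <- nrow(sp); H <- ncol(sp)
  stopifnot(W == H)
  S <- colSums(triSites)          # 3 * centroid
  out <- matrix(-1L, W, H)
  for (j in 0:(H - 1L)) for (i in 0:(W - 1L)) {
    s <- sp[i + 1L, j + 1L]
    if (s < 0L) next
    # q = 3p - S; rotate by 240 deg = R^4 = (i,j) -> (j, -i-j) applied to q;
    # forward image of p under +120 about centroid
    q <- c(3L * i, 3L * j) - S
    rq <- c(-q[1L] - q[2L], q[1L])          # +120 deg: (i,j)->(-i-j, i)
    pp <- (rq + S) / 3L
    stopifnot(pp == round(pp))
    ii <- pp[1L] %% W; jj <- pp[2L] %% H
    out[ii + 1L, jj + 1L] <- (s + 2L) %% 6L
  }
  FilmLattice(out)
}

# rotate a configuration by 180 degrees about the midpoint of two adjacent
# sites (2 x 2 matrix of axial coordinates); spins advance by 3.
rotate180About <- function(cfg, bondSites) {
  sp <- spins(cfg)
  W <- nrow(sp); H <- ncol(sp)
  S <- colSums(bondSites)         # 2 * midpoint
  out <- matrix(-1L, W, H)
  for (j in 0:(H - 1L)) for (i in 0:(W - 1L)) {
    s <- sp[i + 1L, j + 1L]
    if (s < 0L) next
    pp <- S - c(i, j)
    ii <- pp[1L] %% W; jj <- pp[2L] %% H
    out[ii + 1L, jj + 1L] <- (s + 3L) %% 6L
  }
  FilmLattice(out)
}

# rotate a configuration by 60 degrees about a lattice site; spins +1
rotate60About <- function(cfg, centre) {
  sp <- spins(cfg)
  W <- nrow(sp); H <- ncol(sp)
  stopifnot(W == H)
  out <- matrix(-1L, W, H)
  for (j in 0:(H - 1L)) for (i in 0:(W - 1L)) {
    s <- sp[i + 1L, j + 1L]
    if (s < 0L) next
    v <- c(i, j) - centre
    rv <- c(-v[2L], v[1L] + v[2L])
    pp <- centre + rv
    out[(pp[1L] %% W) + 1L, (pp[2L] %% H) + 1L] <- (s + 1L) %% 6L
  }
  FilmLattice(out)
}

# synthetic growth series with a filling phase already complete (constant
# occupancy) and no percolation, so the whole series is the steady window
syntheticSeries <- function(sizes, sweeps = seq_along(sizes) - 1L) {
  data.frame(sweep = sweeps, n_occupied = rep(1000L, length(sizes)),
             largest_cluster = as.integer(round(sizes)),
             energy = 0, n_trimer = 0L, n_p6 = 0L, n_p3 = 0L,
             percolated = 0L)
}

# tile a configuration k x k times (periodic replication)
replicateConfig <- function(cfg, k) {
  sp <- spins(cfg)
  FilmLattice(do.call(rbind, rep(list(do.call(cbind, rep(list(sp), k))), k)))
}
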