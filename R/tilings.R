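# Reference crystal tilings on the triangular lattice.
#
# P6 crystal: sqrt(7) vacancy superlattice (generators (2,1) and (-1,3));
# each 7-site cell holds one vacancy, one "up" trimer with the even
# orientations and one "down" trimer (its 180-degree image) with the odd
# orientations. The sublattice of a site is f(i, j) = (i + 5 j) mod 7, which
# vanishes exactly on the vacancy superlattice.
#
# Canonical 7-site cell (relative to the vacancy at (0,0)):
#   up trimer:   (0,1) -> 0, (1,1) -> 2, (0,2) -> 4
#   down trimer: (1,0) -> 5, (2,0) -> 3, (2,-1) -> 1
# i.e. sublattice residue -> spin lookup below.
.P6_LUT <- c(-1L, 5L, 3L, 4L, 1L, 0L, 2L)  # index = f(i,j) + 1

.p6SpinAt <- function(i, j, vacancySublattice = 0L) {
  .P6_LUT[((i - vacancySublattice + 5L * j) %% 7L) + 1L]
}

# inverse 60-degree axial rotation: (i, j) -> (i + j, -i)
.rotInv60 <- function(i, j) list(i = i + j, j = -i)

#' Build the P6 reference tiling (hexamer crystal)
#'
#' Constructs the six-protein-per-cell ground-state crystal: vacancies on
#' the sqrt(7) superlattice translated to the chosen sublattice, each 7-site
#' cell holding one "up" trimer (even orientations) and one "down" trimer
#' (its 180-degree image, odd orientations). Occupancy is exactly 6/7. The
#' seven vacancy sublattices give the seven distinct ordered structures;
#' \code{spinOffset} applies a global rotation by spinOffset * 60 degrees
#' about a vacancy, which is a symmetry operation of the crystal (the
#' tiling has a six-fold axis at every vacancy), so all six offsets of a
#' given sublattice coincide.
#'
#' @param cellsX,cellsY number of 7 x 7-site cells per side (box is
#'   7*cellsX x 7*cellsY sites).
#' @param vacancySublattice which of the 7 sublattices carries the
#'   vacancies (0..6).
#' @param spinOffset global rotation in 60-degree steps (0..5).
#' @return A \linkS4class{FilmLattice}.
#' @examples
#' occupancy(buildP6Tiling(1, 1))   # 6/7
#' @export
buildP6Tiling <- function(cellsX, cellsY = cellsX, vacancySublattice = 0L,
                          spinOffset = 0L) {
  if (cellsX < 1L || cellsY < 1L || cellsX != round(cellsX) ||
      cellsY != round(cellsY))
    stop("cellsX and cellsY must be positive integers (box = multiples of 7 sites)")
  if (!vacancySublattice %in% 0:6) stop("vacancySublattice must be in 0..6")
  if (!spinOffset %in% 0:5) stop("spinOffset must be in 0..5")
  W <- 7L * as.integer(cellsX); H <- 7L * as.integer(cellsY)
  idx <- expand.grid(i = 0:(W - 1L), j = 0:(H - 1L))
  # rotate the base pattern spinOffset times about the origin vacancy, then
  # translate the vacancy lattice to the requested sublattice
  p <- list(i = idx$i - as.integer(vacancySublattice), j = idx$j)
  for (r in seq_len(spinOffset)) p <- .rotInv60(p$i, p$j)
  s <- .p6SpinAt(p$i, p$j)
  s <- ifelse(s >= 0L, (s + as.integer(spinOffset)) %% 6L, -1L)
  FilmLattice(matrix(as.integer(s), nrow = W, ncol = H))
}

#' Build the metastable low-density P3 tiling
#'
#' Same-parity trimers on a 2 x 2 site superlattice: per cell one "up"
#' trimer at offsets (0,0), (1,0), (0,1) carrying orientations 0, 2, 4 (or
#' the 180-degree image with orientations 3, 5, 1 for \code{parity =
#' "down"}), with the fourth site vacant. Occupancy is exactly 3/4 -- the
#' three-protein unit cell of the low-density P3 structure, sparser than the
#' 6/7 of the P6 crystal. The decorated pattern is invariant under
#' 120-degree rotation about each trimer centre but under no 2-fold
#' rotation (plane group p3).
#'
#' @param cellsX,cellsY number of 2 x 2-site cells per side.
#' @param phase translation of the pattern within the 2 x 2 cell (0..3,
#'   offset (phase mod 2, phase div 2)).
#' @param parity "up" or "down" trimers.
#' @return A \linkS4class{FilmLattice}.
#' @examples
#' occupancy(buildP3Tiling(2, 2))   # 3/4
#' @export
buildP3Tiling <- function(cellsX, cellsY = cellsX, phase = 0L,
                          parity = c("up", "down")) {
  parity <- match.arg(parity)
  if (cellsX < 1L || cellsY < 1L || cellsX != round(cellsX) ||
      cellsY != round(cellsY))
    stop("cellsX and cellsY must be positive integers (box = multiples of 2 sites)")
  if (!phase %in% 0:3) stop("phase must be in 0..3")
  W <- 2L * as.integer(cellsX); H <- 2L * as.integer(cellsY)
  px <- as.integer(phase) %% 2L; py <- as.integer(phase) %/% 2L
  idx <- expand.grid(i = 0:(W - 1L), j = 0:(H - 1L))
  u <- (idx$i - px) %% 2L
  w <- (idx$j - py) %% 2L
  s <- if (parity == "up") {
    # (0,0)->0, (1,0)->2, (0,1)->4, (1,1)->vacant
    ifelse(u == 0L & w == 0L, 0L,
    ifelse(u == 1L & w == 0L, 2L,
    ifelse(u == 0L & w == 1L, 4L, -1L)))
  } else {
    # 180-degree image: (1,1)->3, (0,1)->5, (1,0)->1, (0,0)->vacant
    ifelse(u == 1L & w == 1L, 3L,
    ifelse(u == 0L & w == 1L, 5L,
    ifelse(u == 1L & w == 0L, 1L, -1L)))
  }
  FilmLattice(matrix(as.integer(s), nrow = W, ncol = H))
}

# All ordered occupied adjacent triples (d, si, sj) realized in a
# configuration; returns a 3-column integer matrix.
.scanTriples <- function(cfg) {
  sp <- spins(cfg)
  W <- nrow(sp); H <- ncol(sp)
  out <- vector("list", 6L)
  for (d in 0:5) {
    # neighbour of (i, j) in direction d, with periodic wrap
    ii <- ((0:(W - 1L)) + .DX[d + 1L]) %% W
    jj <- ((0:(H - 1L)) + .DY[d + 1L]) %% H
    nbr <- sp[ii + 1L, jj + 1L, drop = FALSE]
    keep <- sp >= 0L & nbr >= 0L
    if (any(keep))
      out[[d + 1L]] <- cbind(d = d, si = sp[keep], sj = nbr[keep])
  }
  res <- do.call(rbind, out)
  if (is.null(res)) matrix(integer(0), ncol = 3L,
                           dimnames = list(NULL, c("d", "si", "sj")))
  else res
}
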