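# Synthetic fixture generators: random adsorbate gases, two-domain
# configurations and defected crystals. All fixtures have finite energy
# under their stated tables and are bit-reproducible from the seed.

#' Random valid adsorbate gas
#'
#' Sequential random insertion of random-orientation proteins at random
#' vacant sites, rejecting insertions that would create a forbidden
#' contact, until the target density is reached or attempts saturate
#' (rejection sampling, not equilibration -- equilibrium states come from
#' \code{\link{runSimulation}}). Finite energy is guaranteed by
#' construction; the achieved density is stored in the metadata.
#'
#' @param width,height lattice dimensions in sites.
#' @param density target occupied fraction in [0, 1].
#' @param seed RNG seed.
#' @param table an \linkS4class{InteractionTable}.
#' @return A \linkS4class{FilmLattice} with metadata fields
#'   \code{achieved_density} and \code{seed}.
#' @export
makeRandomConfig <- function(width, height, density, seed,
                             table = buildInteractionTable(TRUE)) {
  if (density < 0 || density > 1) stop("density must be in [0, 1]")
  set.seed(seed)
  sp <- cpp_random_config(as.integer(width), as.integer(height), density,
                          as.integer(tableClasses(table)))
  FilmLattice(sp, metadata = list(kind = "random_gas",
                                  achieved_density = sum(sp >= 0L) / length(sp),
                                  seed = seed))
}

#' Two P6 domains on mismatched sublattices
#'
#' Left half of the box holds a P6 crystal with vacancies on sublattice A,
#' right half on sublattice B, separated by vacant strips of the given
#' width (two strips, since the box is periodic). The two crystals cannot
#' bond directly across the gap, so they form distinct clusters; in
#' simulations with P3 docking enabled, adsorption into the boundary region
#' can glue the mismatched domains together -- the domain-boundary
#' mechanism behind exponential network growth. Whether a single adsorbed
#' protein can bridge a gap of 1 depends on the relative shift of the two
#' domains: e.g. the pair (0, 2) is bridgeable through a P3 dock, while
#' (0, 3) offers no allowed boundary adsorption at all.
#'
#' @param cellsX,cellsY box size in 7 x 7-site cells; cellsX must be even
#'   so the box splits into two equal halves.
#' @param sublatticeA,sublatticeB vacancy sublattices (0..6) of the two
#'   domains; must differ.
#' @param gap width of each vacant strip in sites (>= 1).
#' @param seed stored in the metadata for provenance (the construction is
#'   deterministic).
#' @return A \linkS4class{FilmLattice}.
#' @export
makeTwoDomainConfig <- function(cellsX, cellsY = cellsX, sublatticeA = 0L,
                                sublatticeB = 1L, gap = 2L, seed = 0L) {
  if (sublatticeA == sublatticeB) stop("the two sublattices must differ")
  if (!sublatticeA %in% 0:6 || !sublatticeB %in% 0:6)
    stop("sublattices must be in 0..6")
  if (gap < 1L) stop("gap must be >= 1")
  if (cellsX %% 2L != 0L) stop("cellsX must be even (two equal halves)")
  W <- 7L * as.integer(cellsX); H <- 7L * as.integer(cellsY)
  half <- W %/% 2L
  if (half - gap < 7L) stop("box too small for the requested gap")
  A <- spins(buildP6Tiling(cellsX, cellsY, sublatticeA))
  B <- spins(buildP6Tiling(cellsX, cellsY, sublatticeB))
  sp <- matrix(.VACANT, nrow = W, ncol = H)
  leftCols <- seq_len(half - gap)               # i = 0 .. half-gap-1
  rightCols <- (half + 1L):(W - gap)            # i = half .. W-gap-1
  sp[leftCols, ] <- A[leftCols, ]
  sp[rightCols, ] <- B[rightCols, ]
  FilmLattice(sp, metadata = list(kind = "two_domain",
                                  sublattices = c(sublatticeA, sublatticeB),
                                  gap = gap, seed = seed))
}

#' Reference tiling with random vacancies
#'
#' Removes each occupied site of a reference crystal independently with the
#' given probability -- robustness input for the cluster and growth
#' analytics.
#'
#' @param base "p6" or "p3".
#' @param cells cells per side of the reference tiling.
#' @param defectFraction removal probability in [0, 1).
#' @param seed RNG seed.
#' @return A \linkS4class{FilmLattice}.
#' @export
makeDefectedTiling <- function(base = c("p6", "p3"), cells, defectFraction,
                               seed) {
  base <- match.arg(base)
  if (defectFraction < 0 || defectFraction >= 1)
    stop("defectFraction must be in [0, 1)")
  cfg <- if (base == "p6") buildP6Tiling(cells, cells)
         else buildP3Tiling(cells, cells)
  sp <- spins(cfg)
  set.seed(seed)
  occ <- which(sp >= 0L)
  kill <- occ[runif(length(occ)) < defectFraction]
  sp[kill] <- .VACANT
  FilmLattice(sp, metadata = list(kind = "defected", base = base,
                                  defect_fraction = defectFraction,
                                  seed = seed))
}
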