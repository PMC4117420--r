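#' Lattice configuration of the simulated film
#'
#' A periodic triangular lattice of sites, each vacant (-1) or carrying one
#' of six protein orientations (0..5, orientation k = rotation by k * 60
#' degrees). The spin at axial coordinate (i, j) (0-based) is stored at
#' matrix position [i + 1, j + 1].
#'
#' @slot spins integer matrix, dim = c(width, height), values in {-1, 0..5}.
#' @slot metadata list of free-form provenance notes (e.g. achieved density
#'   of a random fixture).
#' @export
setClass("FilmLattice",
         representation(spins = "matrix", metadata = "list"),
         prototype(metadata = list()))

setValidity("FilmLattice", function(object) {
  s <- object@spins
  if (!is.matrix(s) || !is.numeric(s)) return("spins must be an integer matrix")
  if (nrow(s) < 2L || ncol(s) < 2L) return("lattice must be at least 2 x 2 sites")
  if (any(s != round(s)) || any(s < -1L) || any(s > 5L))
    return("spin values must be in {-1, 0..5}")
  TRUE
})

#' Construct a FilmLattice from a spin matrix
#'
#' @param spins integer matrix with values in {-1, 0..5}; -1 marks a vacant
#'   site. Row index is the first axial coordinate (i), column index the
#'   second (j), both 0-based in lattice terms.
#' @param metadata optional list of provenance notes.
#' @return A \linkS4class{FilmLattice}.
#' @export
FilmLattice <- function(spins, metadata = list()) {
  storage.mode(spins) <- "integer"
  new("FilmLattice", spins = spins, metadata = metadata)
}

#' Empty lattice of a given size
#'
#' @param width,height site counts along the two axial directions (>= 2).
#' @return A vacant \linkS4class{FilmLattice}.
#' @export
emptyLattice <- function(width, height = width) {
  FilmLattice(matrix(.VACANT, nrow = width, ncol = height))
}

#' Interaction classification table of the spin model
#'
#' Classifies every (bond direction, orientation pair) as trimer, P6 dock,
#' P3 dock, or forbidden. Built constructively from the two reference
#' crystal tilings by \code{\link{buildInteractionTable}}.
#'
#' @slot cls integer array, dim = c(6, 6, 6); entry [d+1, si+1, sj+1] is the
#'   class of a bond from a spin si to the neighbour at direction d carrying
#'   spin sj: 0 forbidden, 1 trimer, 2 P6 dock, 3 P3 dock.
#' @slot p3Enabled logical; whether P3 docking entries are present.
#' @export
setClass("InteractionTable",
         representation(cls = "array", p3Enabled = "logical"))

setValidity("InteractionTable", function(object) {
  cls <- object@cls
  if (!identical(dim(cls), c(6L, 6L, 6L))) return("cls must be a 6 x 6 x 6 array")
  if (any(!cls %in% 0:3)) return("class codes must be in 0..3")
  for (d in 1:6) for (si in 1:6) for (sj in 1:6) {
    if (cls[d, si, sj] != cls[(d + 2L) %% 6L + 1L, sj, si])
      return("reciprocity violated: cls(d, si, sj) != cls(opposite(d), sj, si)")
  }
  for (si in 1:6)
    if (sum(cls[, si, ] == 1L) != 2L)
      return("each orientation must have exactly 2 trimer-capable entries")
  if (!object@p3Enabled && any(cls == 3L))
    return("P3 dock entries present although p3Enabled is FALSE")
  TRUE
})

#' Construct an InteractionTable from an explicit class array
#'
#' Mostly useful for constructing modified tables in tests or sensitivity
#' studies; the model's own table comes from
#' \code{\link{buildInteractionTable}}.
#'
#' @param cls integer 6 x 6 x 6 array of class codes (see
#'   \linkS4class{InteractionTable}).
#' @param p3Enabled logical flag.
#' @return An \linkS4class{InteractionTable}.
#' @export
interactionTable <- function(cls, p3Enabled = any(cls == 3L)) {
  storage.mode(cls) <- "integer"
  new("InteractionTable", cls = cls, p3Enabled = p3Enabled)
}

#' Coupling constants of the spin model
#'
#' Couplings are stored as positive magnitudes and enter the energy with a
#' leading minus sign: E = -J0*nT - J1*nP6 - J2*nP3 - Jsurf*N. Units are kT
#' (the engine's inverse temperature beta defaults to 1). Defaults are the
#' study values J0 = 5, J1 = 2, J2 = 1, Jsurf = 10.
#'
#' @slot J0 trimer coupling (kT).
#' @slot J1 P6 docking coupling (kT).
#' @slot J2 P3 docking coupling (kT).
#' @slot Jsurf adsorption benefit magnitude (kT).
#' @slot pAbsent probability in [0, 1] that an attempted adsorption finds no
#'   protein available (subsaturated bulk); 0 = saturated.
#' @export
setClass("ModelParams",
         representation(J0 = "numeric", J1 = "numeric", J2 = "numeric",
                        Jsurf = "numeric", pAbsent = "numeric"))

setValidity("ModelParams", function(object) {
  v <- c(object@J0, object@J1, object@J2, object@Jsurf, object@pAbsent)
  if (length(v) != 5L || any(!is.finite(v))) return("all parameters must be finite scalars")
  if (any(c(object@J0, object@J1, object@J2, object@Jsurf) < 0))
    return("couplings are stored as nonnegative magnitudes")
  if (object@pAbsent < 0 || object@pAbsent > 1) return("pAbsent must be in [0, 1]")
  TRUE
})

#' @param J0,J1,J2,Jsurf coupling magnitudes in kT.
#' @param pAbsent adsorption-thinning probability in [0, 1].
#' @return A \linkS4class{ModelParams}.
#' @rdname ModelParams-class
#' @export
modelParams <- function(J0 = 5, J1 = 2, J2 = 1, Jsurf = 10, pAbsent = 0) {
  new("ModelParams", J0 = J0, J1 = J1, J2 = J2, Jsurf = Jsurf,
      pAbsent = pAbsent)
}

#' Monte Carlo run parameters
#'
#' @slot sweeps number of sweeps; one sweep = width * height attempted moves.
#' @slot seed RNG seed (run is bit-reproducible given the seed).
#' @slot beta inverse temperature (default 1, so couplings are in kT).
#' @slot moveMix weights of the three move classes
#'   (adsorb/desorb, hop/rotate, trimer); default c(0.4, 0.4, 0.2).
#' @slot recordEvery sweeps between observable records (default 1).
#' @export
setClass("MCParams",
         representation(sweeps = "integer", seed = "integer", beta = "numeric",
                        moveMix = "numeric", recordEvery = "integer"))

setValidity("MCParams", function(object) {
  if (object@sweeps < 0L) return("sweeps must be >= 0")
  if (length(object@moveMix) != 3L || any(object@moveMix < 0) ||
      sum(object@moveMix) <= 0)
    return("moveMix must be 3 nonnegative weights with positive sum")
  if (!is.finite(object@beta) || object@beta < 0) return("beta must be >= 0")
  if (object@recordEvery < 1L) return("recordEvery must be >= 1")
  TRUE
})

#' @param sweeps,seed,beta,moveMix,recordEvery see slots.
#' @return An \linkS4class{MCParams}.
#' @rdname MCParams-class
#' @export
mcParams <- function(sweeps, seed = 1L, beta = 1,
                     moveMix = c(0.4, 0.4, 0.2), recordEvery = 1L) {
  new("MCParams", sweeps = as.integer(sweeps), seed = as.integer(seed),
      beta = beta, moveMix = as.numeric(moveMix),
      recordEvery = as.integer(recordEvery))
}

#' Continuous-space hexagonal lattice
#'
#' @slot a lattice parameter in Angstrom.
#' @slot gamma inter-axis angle in degrees, fixed at 120.
#' @export
setClass("HexLattice2D", representation(a = "numeric", gamma = "numeric"))

setValidity("HexLattice2D", function(object) {
  if (!is.finite(object@a) || object@a <= 0) return("lattice parameter a must be > 0")
  if (object@gamma != 120) return("gamma is fixed at 120 degrees")
  TRUE
})

#' @param a lattice parameter in Angstrom (> 0).
#' @return A \linkS4class{HexLattice2D}.
#' @rdname HexLattice2D-class
#' @export
hexLattice <- function(a) new("HexLattice2D", a = a, gamma = 120)

#' Six-parameter description of the P6 hexamer
#'
#' The protein arrangement within P6 symmetry: two trimers related by a
#' 2-fold axis. Parameters: the three Euler angles of a protein relative to
#' the radial axis from its trimer centre (the planar reduction uses only
#' the in-plane angle; the two out-of-plane angles are carried but fixed at
#' 0), the protein-to-trimer-centre distance, the distance between the two
#' trimer centres, and the rotation angle of the trimer pair about the
#' inter-centre axis.
#'
#' @slot euler numeric(3), radians; euler[2:3] must be 0 in planar use.
#' @slot rTrimer protein-to-trimer-centre distance, Angstrom (> 0).
#' @slot dTrimers distance between the two trimer centres, Angstrom (> 0).
#' @slot psi rotation angle of the two trimers, radians.
#' @export
setClass("P6Params",
         representation(euler = "numeric", rTrimer = "numeric",
                        dTrimers = "numeric", psi = "numeric"))

setValidity("P6Params", function(object) {
  if (length(object@euler) != 3L || any(!is.finite(object@euler)))
    return("euler must be 3 finite angles")
  if (any(object@euler[2:3] != 0))
    return("out-of-plane Euler angles are fixed at 0 in the planar model")
  if (!is.finite(object@rTrimer) || object@rTrimer <= 0) return("rTrimer must be > 0")
  if (!is.finite(object@dTrimers) || object@dTrimers <= 0) return("dTrimers must be > 0")
  TRUE
})

#' @param euler,rTrimer,dTrimers,psi see slots.
#' @return A \linkS4class{P6Params}.
#' @rdname P6Params-class
#' @export
p6Params <- function(rTrimer, dTrimers, psi = 0, euler = c(0, 0, 0)) {
  new("P6Params", euler = euler, rTrimer = rTrimer, dTrimers = dTrimers,
      psi = psi)
}

#' Cluster labelling of a lattice configuration
#'
#' Clusters are connected components over attractive bonds (trimer, P6 dock,
#' P3 dock) -- a cluster of interacting spins, not mere adjacency. Winding
#' of a cluster around either periodic direction marks percolation.
#'
#' @slot labels integer matrix (same dim as the lattice); 0 = vacant,
#'   1..K = cluster id.
#' @slot sizes integer vector of cluster sizes (by cluster id).
#' @slot wraps logical vector; TRUE if the cluster wraps the torus.
#' @export
setClass("ClusterLabeling",
         representation(labels = "matrix", sizes = "integer",
                        wraps = "logical"))

setValidity("ClusterLabeling", function(object) {
  if (length(object@sizes) != length(object@wraps))
    return("sizes and wraps must have one entry per cluster")
  if (sum(object@sizes) != sum(object@labels > 0L))
    return("cluster sizes must sum to the number of labelled sites")
  TRUE
})

#' Linear-versus-exponential growth classification
#'
#' Least-squares fits of largest-cluster size against Monte Carlo time on a
#' steady-state window, compared by corrected AIC (both models measured on
#' the same observation scale; the log-model likelihood includes the
#' Jacobian of the log transform).
#'
#' @slot window numeric(2): first and last sweep of the fitted window.
#' @slot linearFit numeric(2): intercept and slope of size ~ sweep.
#' @slot linearSE numeric(2): standard errors of the linear coefficients.
#' @slot linearAICc corrected AIC of the linear model.
#' @slot expFit numeric(2): log-intercept and rate of log(size) ~ sweep.
#' @slot expAICc corrected AIC of the exponential model.
#' @slot label "linear", "exponential" or "indeterminate" (|delta AICc| < 2).
#' @slot nPoints number of records fitted.
#' @slot note diagnostic message (e.g. why a window was indeterminate).
#' @export
setClass("GrowthFit",
         representation(window = "numeric", linearFit = "numeric",
                        linearSE = "numeric", linearAICc = "numeric",
                        expFit = "numeric", expAICc = "numeric",
                        label = "character", nPoints = "integer",
                        note = "character"))

#' Scenario description for the film-formation experiments
#'
#' The three computational experiments: \code{p6_only} (only the P6 crystal
#' permitted), \code{p6_p3} (both P6 and the metastable P3 structure
#' permitted) and \code{subsaturated} (P6 + P3 with adsorption thinned by
#' pAbsent = 0.5, emulating protein availability of 50 percent).
#'
#' @slot name one of "p6_only", "p6_p3", "subsaturated".
#' @slot cells unit cells per side; each cell is 14 x 14 sites (default 40,
#'   the full-scale system; 10 is a desk-scale preset).
#' @slot sweeps Monte Carlo sweeps per run.
#' @slot seeds integer vector of RNG seeds (one run per seed).
#' @slot params \linkS4class{ModelParams} for the runs.
#' @slot beta inverse temperature.
#' @slot recordEvery sweeps between records.
#' @export
setClass("FilmScenario",
         representation(name = "character", cells = "integer",
                        sweeps = "integer", seeds = "integer",
                        params = "ModelParams", beta = "numeric",
                        recordEvery = "integer"))

setValidity("FilmScenario", function(object) {
  if (!object@name %in% c("p6_only", "p6_p3", "subsaturated"))
    return("name must be p6_only, p6_p3 or subsaturated")
  if (object@cells < 2L) return("cells must be >= 2")
  if (object@sweeps < 0L) return("sweeps must be >= 0")
  if (length(object@seeds) < 1L) return("at least one seed is required")
  if (object@name == "subsaturated" && object@params@pAbsent != 0.5)
    return("subsaturated scenario requires pAbsent = 0.5")
  TRUE
})
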