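#' Run the Metropolis Monte Carlo simulation
#'
#' Executes \code{sweeps} sweeps of the protein-mimicking dynamics; one
#' sweep is width * height attempted moves. Each attempt draws a move class
#' by the move-mix weights:
#' \itemize{
#'   \item \strong{adsorb/desorb}: pick a uniform site. If vacant, with
#'     probability \code{pAbsent} nothing happens (no protein available in
#'     the subphase); otherwise a uniform orientation is proposed. If
#'     occupied, removal is proposed. Acceptance uses the
#'     Metropolis-Hastings ratio min(1, 6 exp(-beta dE)) for insertion and
#'     min(1, exp(-beta dE)/6) for deletion -- the factor 6 compensates the
#'     1/6 proposal probability of each orientation so that detailed
#'     balance holds with respect to the stated energy.
#'   \item \strong{hop/rotate}: pick a uniform occupied site; propose a
#'     target uniformly from \{stay, 6 neighbours\} x \{keep, +60, -60\}
#'     excluding the null proposal (20 options); hops to occupied sites are
#'     rejected. Acceptance min(1, exp(-beta dE)).
#'   \item \strong{trimer}: pick a uniform complete trimer (via a uniform
#'     occupied site, rejecting sites not in a complete trimer -- each
#'     trimer has 3 member sites, so trimers are drawn uniformly); propose
#'     rigid translation by a uniform direction and/or rotation of all
#'     three orientations by +-60 degrees about a uniformly chosen member
#'     pivot; target sites must be vacant or belong to the moving trimer.
#' }
#' Moves creating forbidden contacts are rejected (dE = +Inf). Observables
#' (occupancy, largest attractively-bonded cluster, running energy, bond
#' census, percolation) are recorded at sweep 0 and every
#' \code{recordEvery} sweeps. Fully reproducible from the seed.
#'
#' @param initial a finite-energy \linkS4class{FilmLattice} start
#'   configuration.
#' @param table an \linkS4class{InteractionTable}.
#' @param mp a \linkS4class{ModelParams}.
#' @param mc an \linkS4class{MCParams}.
#' @return List with elements \code{series} (data.frame with columns sweep,
#'   n_occupied, largest_cluster, energy, n_trimer, n_p6, n_p3, percolated)
#'   and \code{final} (\linkS4class{FilmLattice}).
#' @export
runSimulation <- function(initial, table, mp, mc) {
  stopifnot(is(initial, "FilmLattice"), is(table, "InteractionTable"),
            is(mp, "ModelParams"), is(mc, "MCParams"))
  if (!is.finite(configEnergy(initial, table, mp)))
    stop("initial configuration has infinite energy under this table")
  set.seed(mc@seed)
  res <- cpp_run_simulation(spins(initial), as.integer(tableClasses(table)),
                            c(mp@J0, mp@J1, mp@J2), mp@Jsurf, mp@pAbsent,
                            mc@beta, mc@sweeps, mc@moveMix, mc@recordEvery)
  rec <- t(res$records)
  series <- data.frame(sweep = as.integer(rec[, 1L]),
                       n_occupied = as.integer(rec[, 2L]),
                       largest_cluster = as.integer(rec[, 3L]),
                       energy = rec[, 4L],
                       n_trimer = as.integer(rec[, 5L]),
                       n_p6 = as.integer(rec[, 6L]),
                       n_p3 = as.integer(rec[, 7L]),
                       percolated = as.integer(rec[, 8L]))
  list(series = series, final = FilmLattice(res$final))
}

#' Zero-temperature quench
#'
#' Repeats sweeps at beta -> infinity (only strictly energy-lowering moves
#' are accepted) until one full sweep accepts nothing. Deterministic given
#' the seed. Useful for metastability analysis: configurations that survive
#' a quench unchanged are local energy minima under the move set.
#'
#' @inheritParams runSimulation
#' @param cfg a finite-energy \linkS4class{FilmLattice}.
#' @param seed RNG seed.
#' @param moveMix weights of the three move classes.
#' @param maxSweeps safety cap on the number of sweeps.
#' @return The quenched \linkS4class{FilmLattice}.
#' @export
quench <- function(cfg, table, mp, seed = 1L, moveMix = c(0.4, 0.4, 0.2),
                   maxSweeps = 10000L) {
  stopifnot(is(cfg, "FilmLattice"), is(table, "InteractionTable"),
            is(mp, "ModelParams"))
  if (!is.finite(configEnergy(cfg, table, mp)))
    stop("configuration has infinite energy under this table")
  set.seed(seed)
  res <- cpp_quench(spins(cfg), as.integer(tableClasses(table)),
                    c(mp@J0, mp@J1, mp@J2), mp@Jsurf, moveMix,
                    as.integer(maxSweeps))
  FilmLattice(res$final)
}
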