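#' Total energy of a configuration
#'
#' E = -J0*nT - J1*nP6 - J2*nP3 - Jsurf*N where nT, nP6, nP3 count unordered
#' occupied adjacent pairs of each attractive class and N counts occupied
#' sites; +Inf if any occupied adjacent pair is forbidden.
#'
#' @param cfg a \linkS4class{FilmLattice}.
#' @param table an \linkS4class{InteractionTable}.
#' @param mp a \linkS4class{ModelParams}.
#' @return Energy in kT units (possibly +Inf).
#' @export
configEnergy <- function(cfg, table, mp = modelParams()) {
  cpp_config_energy(spins(cfg), as.integer(tableClasses(table)),
                    c(mp@J0, mp@J1, mp@J2), mp@Jsurf)
}

#' Census of bonds and occupancy
#'
#' Counts the unordered occupied adjacent pairs of each interaction class
#' (each pair counted once) and the occupied sites.
#'
#' @inheritParams configEnergy
#' @return Named integer vector: n_trimer, n_p6, n_p3, n_forbidden,
#'   n_occupied.
#' @export
bondCensus <- function(cfg, table) {
  cpp_bond_census(spins(cfg), as.integer(tableClasses(table)))
}

#' Trial-move descriptions
#'
#' Constructors for the three protein-mimicking move classes of the Monte
#' Carlo engine, for use with \code{\link{deltaEnergy}} and
#' \code{\link{applyMove}}. Site coordinates are 0-based axial lattice
#' coordinates.
#'
#' @param i,j axial coordinates of the picked site (for trimer moves, any
#'   member of the trimer).
#' @param orientation spin value 0..5 to adsorb.
#' @param dir hop/translation direction 0..5, or NA for none.
#' @param rot rotation in 60-degree steps: -1, 0 or +1.
#' @param pivot for trimer rotations, which member site (0..2, in role
#'   order spin s, s+2, s+4) is the rotation pivot.
#' @return A move description (named list).
#' @name moves
NULL

#' @rdname moves
#' @export
moveAdsorb <- function(i, j, orientation) {
  list(type = "adsorb", i = as.integer(i), j = as.integer(j),
       orientation = as.integer(orientation))
}

#' @rdname moves
#' @export
moveDesorb <- function(i, j) {
  list(type = "desorb", i = as.integer(i), j = as.integer(j))
}

#' @rdname moves
#' @export
moveHop <- function(i, j, dir = NA_integer_, rot = 0L) {
  list(type = "hop", i = as.integer(i), j = as.integer(j),
       dir = as.integer(dir), rot = as.integer(rot))
}

#' @rdname moves
#' @export
moveTrimer <- function(i, j, dir = NA_integer_, rot = 0L, pivot = 0L) {
  list(type = "trimer", i = as.integer(i), j = as.integer(j),
       dir = as.integer(dir), rot = as.integer(rot), pivot = as.integer(pivot))
}

.siteIndex <- function(cfg, i, j) {
  W <- latticeWidth(cfg); H <- latticeHeight(cfg)
  if (is.na(i) || is.na(j) || i < 0L || i >= W || j < 0L || j >= H)
    stop("site (", i, ", ", j, ") outside the ", W, " x ", H, " lattice")
  as.integer(i + W * j)
}

.encodeMove <- function(cfg, move) {
  if (!is.list(move) || is.null(move$type)) stop("malformed move description")
  sp <- spins(cfg)
  site <- .siteIndex(cfg, move$i, move$j)
  occ <- sp[site + 1L] >= 0L
  switch(move$type,
    adsorb = {
      if (occ) stop("adsorption onto an occupied site")
      if (!move$orientation %in% 0:5) stop("orientation must be in 0..5")
      c(0L, site, move$orientation, 0L, 0L)
    },
    desorb = {
      if (!occ) stop("desorption from a vacant site")
      c(1L, site, 0L, 0L, 0L)
    },
    hop = {
      if (!occ) stop("hop from a vacant site")
      d <- if (is.na(move$dir)) -1L else as.integer(move$dir)
      if (!d %in% c(-1L, 0:5)) stop("dir must be 0..5 or NA")
      if (!move$rot %in% c(-1L, 0L, 1L)) stop("rot must be -1, 0 or +1")
      if (d < 0L && move$rot == 0L) stop("null move (no hop, no rotation)")
      c(2L, site, d, move$rot, 0L)
    },
    trimer = {
      if (!occ) stop("trimer move from a vacant site")
      d <- if (is.na(move$dir)) -1L else as.integer(move$dir)
      if (!d %in% c(-1L, 0:5)) stop("dir must be 0..5 or NA")
      if (!move$rot %in% c(-1L, 0L, 1L)) stop("rot must be -1, 0 or +1")
      if (!move$pivot %in% 0:2) stop("pivot must be 0..2")
      if (d < 0L && move$rot == 0L) stop("null move (no translation, no rotation)")
      c(3L, site, d, move$rot, move$pivot)
    },
    stop("unknown move type: ", move$type))
}

#' Energy change of a trial move
#'
#' Incremental (local) evaluation of the energy difference a move would
#' cause; exactly equals configEnergy(after) - configEnergy(before).
#' Proposals that would create a forbidden contact, or whose target site is
#' occupied, return +Inf.
#'
#' @inheritParams configEnergy
#' @param move a move description from \code{\link{moveAdsorb}},
#'   \code{\link{moveDesorb}}, \code{\link{moveHop}} or
#'   \code{\link{moveTrimer}}.
#' @return Energy difference in kT units (possibly +Inf).
#' @export
deltaEnergy <- function(cfg, table, mp, move) {
  enc <- .encodeMove(cfg, move)
  if (enc[1L] == 3L) {
    ok <- cpp_is_complete_trimer(spins(cfg), as.integer(tableClasses(table)),
                                 enc[2L])
    if (!ok) stop("site is not part of a complete trimer")
  }
  cpp_delta_energy(spins(cfg), as.integer(tableClasses(table)),
                   c(mp@J0, mp@J1, mp@J2), mp@Jsurf, enc)
}

# axial rotation by rot * 60 degrees: +60: (i,j) -> (-j, i+j); -60: (i,j) -> (i+j, -i)
.rotAxial <- function(v, rot) {
  if (rot == 1L) c(-v[2L], v[1L] + v[2L])
  else if (rot == -1L) c(v[1L] + v[2L], -v[1L])
  else v
}

#' Apply a trial move to a configuration
#'
#' Returns the configuration after the move, regardless of its energy (use
#' \code{\link{deltaEnergy}} to evaluate acceptance). Errors if the move is
#' malformed or geometrically impossible (target occupied by a foreign
#' protein).
#'
#' @inheritParams deltaEnergy
#' @return A \linkS4class{FilmLattice}.
#' @export
applyMove <- function(cfg, table, move) {
  enc <- .encodeMove(cfg, move)       # validates
  sp <- spins(cfg)
  W <- nrow(sp); H <- ncol(sp)
  at <- function(i, j) sp[(i %% W) + 1L, (j %% H) + 1L]
  set <- function(i, j, v) sp[(i %% W) + 1L, (j %% H) + 1L] <<- as.integer(v)
  i <- move$i; j <- move$j
  s <- at(i, j)
  switch(move$type,
    adsorb = set(i, j, move$orientation),
    desorb = set(i, j, -1L),
    hop = {
      d <- move$dir
      s2 <- (s + move$rot) %% 6L
      if (is.na(d)) set(i, j, s2)
      else {
        ti <- i + .DX[d + 1L]; tj <- j + .DY[d + 1L]
        if (at(ti, tj) >= 0L) stop("hop target is occupied")
        set(i, j, -1L); set(ti, tj, s2)
      }
    },
    trimer = {
      tri <- .trimerMembers(cfg, table, i, j)
      if (is.null(tri)) stop("site is not part of a complete trimer")
      rot <- move$rot
      piv <- tri$rel[move$pivot + 1L, ]
      newrel <- t(apply(tri$rel, 1L, function(v)
        piv + .rotAxial(v - piv, rot)))
      if (!is.na(move$dir)) {
        newrel[, 1L] <- newrel[, 1L] + .DX[move$dir + 1L]
        newrel[, 2L] <- newrel[, 2L] + .DY[move$dir + 1L]
      }
      newabs <- cbind((tri$base[1L] + newrel[, 1L]) %% W,
                      (tri$base[2L] + newrel[, 2L]) %% H)
      oldabs <- cbind((tri$base[1L] + tri$rel[, 1L]) %% W,
                      (tri$base[2L] + tri$rel[, 2L]) %% H)
      oldkey <- oldabs[, 1L] + W * oldabs[, 2L]
      for (k in 1:3) {
        key <- newabs[k, 1L] + W * newabs[k, 2L]
        if (at(newabs[k, 1L], newabs[k, 2L]) >= 0L && !key %in% oldkey)
          stop("trimer target site is occupied")
      }
      newspin <- (tri$spin + rot) %% 6L
      for (k in 1:3) set(oldabs[k, 1L], oldabs[k, 2L], -1L)
      for (k in 1:3) set(newabs[k, 1L], newabs[k, 2L], newspin[k])
    })
  FilmLattice(sp, metadata = cfg@metadata)
}

# members of the complete trimer containing (i, j), in role order
# (spins s, s+2, s+4 with s the role-0 spin); NULL if incomplete.
.trimerMembers <- function(cfg, table, i, j) {
  sp <- spins(cfg)
  W <- nrow(sp); H <- ncol(sp)
  s <- sp[i + 1L, j + 1L]
  if (s < 0L) return(NULL)
  d1 <- s; d2 <- (s + 1L) %% 6L
  p2 <- c((i + .DX[d1 + 1L]) %% W, (j + .DY[d1 + 1L]) %% H)
  p3 <- c((i + .DX[d2 + 1L]) %% W, (j + .DY[d2 + 1L]) %% H)
  if (sp[p2[1L] + 1L, p2[2L] + 1L] != (s + 2L) %% 6L) return(NULL)
  if (sp[p3[1L] + 1L, p3[2L] + 1L] != (s + 4L) %% 6L) return(NULL)
  list(base = c(i, j),
       rel = rbind(c(0L, 0L),
                   c(.DX[d1 + 1L], .DY[d1 + 1L]),
                   c(.DX[d2 + 1L], .DY[d2 + 1L])),
       spin = c(s, (s + 2L) %% 6L, (s + 4L) %% 6L))
}

#' Enumerate all trial moves available on a configuration
#'
#' Exhaustive single-move enumeration used for local-minimum and
#' metastability analysis: all adsorptions (vacant site x 6 orientations),
#' all desorptions, all hop/rotate proposals (occupied site x 20
#' target/rotation options) and, optionally, all rigid trimer moves (one
#' per complete trimer x 20 options, rotations taken about each of the 3
#' member pivots).
#'
#' @inheritParams configEnergy
#' @param includeTrimer also enumerate rigid trimer moves.
#' @return List of move descriptions.
#' @export
enumerateMoves <- function(cfg, table, includeTrimer = TRUE) {
  sp <- spins(cfg)
  W <- nrow(sp); H <- ncol(sp)
  moves <- list()
  add <- function(m) moves[[length(moves) + 1L]] <<- m
  opts <- expand.grid(dir = c(NA_integer_, 0:5), rot = c(0L, 1L, -1L))
  opts <- opts[!(is.na(opts$dir) & opts$rot == 0L), ]
  for (j in 0:(H - 1L)) for (i in 0:(W - 1L)) {
    s <- sp[i + 1L, j + 1L]
    if (s < 0L) {
      for (o in 0:5) add(moveAdsorb(i, j, o))
    } else {
      add(moveDesorb(i, j))
      for (k in seq_len(nrow(opts)))
        add(moveHop(i, j, opts$dir[k], opts$rot[k]))
    }
  }
  if (includeTrimer) {
    cl <- as.integer(tableClasses(table))
    occ <- which(sp >= 0L) - 1L
    complete <- cpp_is_complete_trimer(sp, cl, occ)
    for (site in occ[complete]) {
      i <- site %% W; j <- site %/% W
      tri <- .trimerMembers(cfg, table, i, j)
      keys <- (tri$base[1L] + tri$rel[, 1L]) %% W +
              W * ((tri$base[2L] + tri$rel[, 2L]) %% H)
      if (site != min(keys)) next   # one representative per trimer
      for (k in seq_len(nrow(opts))) {
        pivots <- if (opts$rot[k] == 0L) 0L else 0:2
        for (p in pivots) add(moveTrimer(i, j, opts$dir[k], opts$rot[k], p))
      }
    }
  }
  moves
}
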