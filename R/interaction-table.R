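#' Build the interaction classification table
#'
#' Defines the Hamiltonian structure of the spin model constructively from
#' the two reference crystal tilings:
#' \itemize{
#'   \item \strong{Trimer entries}: orientation k doubles as the trimer role
#'     label (even orientations form "up" trimers, odd ones "down" trimers).
#'     The bonds of the canonical up trimer -- spin 0 at (0,1), spin 2 at
#'     (1,1), spin 4 at (0,2) -- are closed under the global 60-degree
#'     rotation (orientation +1, direction +1), which yields exactly two
#'     trimer-capable (direction, partner) entries per orientation: spin s
#'     bonds spin s+2 along direction s and spin s+4 along direction s+1
#'     (mod 6).
#'   \item \strong{P6 dock entries}: exactly the (direction, si, sj) triples
#'     realized between sites of different trimers in the P6 reference
#'     tiling, scanned over all 7 vacancy sublattices and all 6 spin
#'     offsets.
#'   \item \strong{P3 dock entries} (only if \code{p3Enabled}): triples
#'     realized between different trimers in the P3 reference tiling
#'     (all 4 phases, both parities), minus any triple already classified.
#'   \item everything else is \strong{forbidden} (infinite energy).
#' }
#'
#' @param p3Enabled logical; include the metastable P3 docking interactions
#'   (TRUE) or permit only the P6 structure (FALSE).
#' @return An \linkS4class{InteractionTable}.
#' @examples
#' buildInteractionTable(TRUE)    # 12 trimer, 18 P6, 12 P3 ordered entries
#' buildInteractionTable(FALSE)
#' @export
buildInteractionTable <- function(p3Enabled = TRUE) {
  cls <- array(0L, dim = c(6L, 6L, 6L))
  # -- trimer entries from the canonical up-trimer placement --------------
  up <- rbind(c(0L, 1L, 0L),   # (i, j, spin)
              c(1L, 1L, 2L),
              c(0L, 2L, 4L))
  base <- NULL
  for (a in 1:3) for (b in 1:3) {
    if (a == b) next
    dx <- up[b, 1L] - up[a, 1L]; dy <- up[b, 2L] - up[a, 2L]
    base <- rbind(base, c(.dirIndex(dx, dy), up[a, 3L], up[b, 3L]))
  }
  for (r in 0:5) {
    d <- (base[, 1L] + r) %% 6L
    si <- (base[, 2L] + r) %% 6L
    sj <- (base[, 3L] + r) %% 6L
    cls[cbind(d + 1L, si + 1L, sj + 1L)] <- 1L
  }
  # -- P6 dock entries from the hexamer crystal ---------------------------
  for (v in 0:6) for (off in 0:5) {
    tr <- .scanTriples(buildP6Tiling(1L, 1L, v, off))
    new <- cls[tr + 1L] == 0L
    cls[tr[new, , drop = FALSE] + 1L] <- 2L
  }
  # -- P3 dock entries from the low-density crystal -----------------------
  if (p3Enabled) {
    for (ph in 0:3) for (par in c("up", "down")) {
      tr <- .scanTriples(buildP3Tiling(2L, 2L, ph, par))
      new <- cls[tr + 1L] == 0L
      cls[tr[new, , drop = FALSE] + 1L] <- 3L
    }
  }
  new("InteractionTable", cls = cls, p3Enabled = p3Enabled)
}
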