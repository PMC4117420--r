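#' Label clusters of interacting proteins
#'
#' Connected components of the occupied sites over \emph{attractive} bonds
#' (trimer, P6 dock, P3 dock) -- merely adjacent proteins with no allowed
#' interaction (impossible at finite energy) would not be connected. Uses
#' union-find with relative-displacement bookkeeping: a cluster percolates
#' (wraps the periodic box) when a cycle closes with nonzero net winding.
#'
#' @inheritParams configEnergy
#' @return A \linkS4class{ClusterLabeling}.
#' @export
labelClusters <- function(cfg, table) {
  res <- cpp_label_clusters(spins(cfg), as.integer(tableClasses(table)))
  new("ClusterLabeling", labels = res$labels,
      sizes = as.integer(res$sizes), wraps = as.logical(res$wraps))
}

#' Size of the largest cluster
#'
#' @param labeling a \linkS4class{ClusterLabeling}.
#' @return Integer count (0 for an empty lattice).
#' @export
largestClusterSize <- function(labeling) {
  stopifnot(is(labeling, "ClusterLabeling"))
  if (length(labeling@sizes) == 0L) return(0L)
  max(labeling@sizes)
}

#' Does any cluster percolate the periodic box?
#'
#' TRUE iff some cluster wraps either periodic direction -- the proxy for a
#' film-spanning elastic protein network.
#'
#' @inheritParams largestClusterSize
#' @return Logical flag.
#' @export
detectPercolation <- function(labeling) {
  stopifnot(is(labeling, "ClusterLabeling"))
  any(labeling@wraps)
}
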