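# Plain-text exchange formats: snapshot TSV for lattice configurations and
# CSV for observable time series. Snapshot round-trips are bit-exact.

#' Write a lattice snapshot (TSV)
#'
#' Format: header lines \code{#width <int>} and \code{#height <int>}, then
#' \code{height} lines of \code{width} tab-separated integers (-1 vacant,
#' 0..5 orientations); line j lists sites (0..width-1, j).
#'
#' @param cfg a \linkS4class{FilmLattice}.
#' @param path output file.
#' @export
writeSnapshot <- function(cfg, path) {
  sp <- spins(cfg)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("#width", nrow(sp)), paste("#height", ncol(sp))), con)
  # one line per j (row of the film), entries i = 0..width-1
  writeLines(apply(sp, 2L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a lattice snapshot (TSV)
#'
#' @param path file written by \code{\link{writeSnapshot}}.
#' @return A \linkS4class{FilmLattice}.
#' @export
readSnapshot <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !startsWith(lines[1L], "#width") ||
      !startsWith(lines[2L], "#height"))
    stop("not a snapshot file: ", path)
  W <- as.integer(sub("#width ", "", lines[1L]))
  H <- as.integer(sub("#height ", "", lines[2L]))
  body <- lines[3:(2L + H)]
  sp <- vapply(strsplit(body, "\t", fixed = TRUE), as.integer, integer(W))
  FilmLattice(matrix(as.integer(sp), nrow = W, ncol = H))
}

#' Write an observable time series (CSV)
#'
#' Columns: sweep, n_occupied, largest_cluster, energy, n_trimer, n_p6,
#' n_p3, percolated (0/1).
#'
#' @param series data.frame as returned by \code{\link{runSimulation}}.
#' @param path output file.
#' @export
writeTimeSeries <- function(series, path) {
  cols <- c("sweep", "n_occupied", "largest_cluster", "energy",
            "n_trimer", "n_p6", "n_p3", "percolated")
  stopifnot(all(cols %in% names(series)))
  write.csv(series[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an observable time series (CSV)
#'
#' @param path file written by \code{\link{writeTimeSeries}}.
#' @return data.frame.
#' @export
readTimeSeries <- function(path) read.csv(path)
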