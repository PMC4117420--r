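#' Lattice vectors of a hexagonal 2D lattice
#'
#' Returns the two lattice vectors as 3-component rows: the first along the
#' x axis, the second rotated 120 degrees counterclockwise from it.
#'
#' @param lat a \linkS4class{HexLattice2D}, or a numeric lattice parameter in
#'   Angstrom.
#' @return A 2 x 3 numeric matrix with rows \code{a} and \code{b}; columns
#'   x, y, z (z = 0 for the planar lattice). Values are exact; round to 3
#'   decimals for reporting.
#' @examples
#' round(hexLatticeVectors(54), 3)   # b = (-27, 46.765, 0)
#' @export
hexLatticeVectors <- function(lat) {
  a <- if (is(lat, "HexLattice2D")) lat@a else as.numeric(lat)
  if (length(a) != 1L || !is.finite(a) || a <= 0)
    stop("lattice parameter must be a single positive number")
  out <- rbind(a = c(a, 0, 0),
               b = c(-a / 2, a * sqrt(3) / 2, 0))
  colnames(out) <- c("x", "y", "z")
  out
}

#' Length of a triangular superlattice vector
#'
#' For close-packed discs of diameter d, the translation m*e1 + n*e2 of the
#' triangular lattice has length d * sqrt(m^2 + m*n + n^2). With d = 20 A
#' (the footprint of a hydrophobin on a hydrophobic surface) the (1,1) and
#' (2,1) vectors come to ~35 A and ~53 A, bracketing the experimentally
#' observed ~54-55 A film lattice constant.
#'
#' @param m,n integer coefficients of the superlattice translation; not both
#'   zero.
#' @param d disc (protein) diameter in Angstrom, default 20.
#' @return Length in Angstrom.
#' @examples
#' superlatticeLength(1, 1)   # 34.64 -> ~35 A
#' superlatticeLength(2, 1)   # 52.92 -> ~53 A
#' @export
superlatticeLength <- function(m, n, d = 20) {
  .checkIndex(m, n)
  if (!is.finite(d) || d <= 0) stop("disc diameter must be > 0")
  d * sqrt(m^2 + m * n + n^2)
}

#' Base-lattice sites per supercell
#'
#' Number of triangular-lattice sites in the supercell spanned by
#' m*e1 + n*e2 and its 60-degree rotation, i.e. m^2 + m*n + n^2. The (2,1)
#' supercell hosts 7 sites; removing one per cell leaves the six-protein
#' hexamer crystal.
#'
#' @inheritParams superlatticeLength
#' @return Integer site count.
#' @examples
#' sitesPerSupercell(2, 1)   # 7
#' @export
sitesPerSupercell <- function(m, n) {
  .checkIndex(m, n)
  as.integer(round(m^2 + m * n + n^2))
}

.checkIndex <- function(m, n) {
  if (length(m) != 1L || length(n) != 1L || m != round(m) || n != round(n))
    stop("superlattice index must be a pair of integers")
  if (m == 0 && n == 0) stop("superlattice index (0, 0) is invalid")
  invisible(TRUE)
}

# Smallest L such that translations (L,0) and (0,L) lie in the integer
# lattice spanned by the columns of `basis` (2 x 2 integer matrix).
.minPeriod <- function(basis, Lmax = 200L) {
  inv <- solve(basis)
  for (L in seq_len(Lmax)) {
    x1 <- inv %*% c(L, 0)
    x2 <- inv %*% c(0, L)
    if (all(abs(c(x1, x2) - round(c(x1, x2))) < 1e-9)) return(L)
  }
  stop("no commensurate period found up to ", Lmax)
}

#' Minimum simulation cell commensurate with both crystal structures
#'
#' Exhaustive search for the smallest L x L site box that is simultaneously
#' periodic for the sqrt(7) vacancy superlattice of the P6 crystal
#' (generators (2,1) and (-1,3); smallest L = 7) and for the 2 x 2
#' superlattice of the low-density P3 crystal (smallest L = 2).
#'
#' @return Integer vector c(14, 14).
#' @examples
#' commensurateCell()
#' @export
commensurateCell <- function() {
  L7 <- .minPeriod(cbind(c(2, 1), c(-1, 3)))
  L2 <- .minPeriod(cbind(c(2, 0), c(0, 2)))
  L <- seq_len(200L)
  L <- L[L %% L7 == 0L & L %% L2 == 0L][1L]
  c(L, L)
}

.wrapAngle <- function(x) x %% (2 * pi)

.circMean <- function(x) Arg(sum(exp(1i * x)))

#' Generate the six poses of a P6 hexamer
#'
#' Emits two trimers of three poses each in a canonical frame: the midpoint
#' between the trimer centres at the origin and the inter-centre axis along
#' +x. Trimer 1 has its centre at (-dTrimers/2, 0) and proteins at distance
#' rTrimer from it at 120-degree spacing starting at angle psi; each
#' protein's in-plane orientation is the radial angle plus the in-plane
#' Euler angle. Trimer 2 is the 180-degree rotation of trimer 1 about the
#' origin, so the output is exactly 2-fold symmetric about the midpoint and
#' each trimer exactly 3-fold symmetric about its centre.
#'
#' @param params a \linkS4class{P6Params}.
#' @return data.frame with columns x, y (Angstrom), theta (radians, in
#'   [0, 2*pi)) and trimer (1 or 2); rows ordered trimer 1 k = 0,1,2 then
#'   their 2-fold images.
#' @export
p6GeneratePoses <- function(params) {
  stopifnot(is(params, "P6Params"))
  validObject(params)
  r <- params@rTrimer; d <- params@dTrimers
  alpha <- params@psi + 2 * pi * (0:2) / 3
  c1 <- c(-d / 2, 0)
  x1 <- c1[1] + r * cos(alpha)
  y1 <- c1[2] + r * sin(alpha)
  th1 <- alpha + params@euler[1]
  # 2-fold image about the origin
  data.frame(x = c(x1, -x1), y = c(y1, -y1),
             theta = .wrapAngle(c(th1, th1 + pi)),
             trimer = rep(1:2, each = 3L))
}

#' Fit P6 parameters to six poses
#'
#' Least-squares estimate of the six-parameter hexamer description closest
#' to an arbitrary set of six planar poses, by direct geometric calculation:
#' trimer centres from centroids, radius and angles averaged over the
#' symmetry-equivalent copies (circular means), and the deviation measured
#' as the root-mean-square distance between the input positions and the
#' regenerated ideal P6 positions after optimal rigid superposition.
#'
#' @param poses data.frame with columns x, y, theta (as produced by
#'   \code{\link{p6GeneratePoses}}) and optionally trimer.
#' @param trimerAssignment integer vector of length 6 with values 1 and 2
#'   (three of each) assigning poses to the two trimers; defaults to the
#'   \code{trimer} column of \code{poses}.
#' @return list with elements \code{params} (a \linkS4class{P6Params}) and
#'   \code{deviation} (RMS distance, Angstrom).
#' @export
p6ExtractParams <- function(poses, trimerAssignment = poses$trimer) {
  if (!is.data.frame(poses) || nrow(poses) != 6L ||
      !all(c("x", "y", "theta") %in% names(poses)))
    stop("poses must be a data.frame of 6 rows with columns x, y, theta")
  if (is.null(trimerAssignment) || length(trimerAssignment) != 6L ||
      sum(trimerAssignment == 1L) != 3L || sum(trimerAssignment == 2L) != 3L)
    stop("trimerAssignment must assign exactly 3 poses to each trimer")
  P <- cbind(poses$x, poses$y)
  if (anyDuplicated(round(P, 12L)))
    stop("degenerate input: coincident positions")
  g1 <- trimerAssignment == 1L
  c1 <- colMeans(P[g1, , drop = FALSE])
  c2 <- colMeans(P[!g1, , drop = FALSE])
  d <- sqrt(sum((c2 - c1)^2))
  if (d < 1e-12) stop("degenerate input: coincident trimer centres")
  u <- atan2(c2[2] - c1[2], c2[1] - c1[1])
  vx <- poses$x - ifelse(g1, c1[1], c2[1])
  vy <- poses$y - ifelse(g1, c1[2], c2[2])
  ri <- sqrt(vx^2 + vy^2)
  if (any(ri < 1e-12)) stop("degenerate input: pose coincides with its trimer centre")
  ang <- atan2(vy, vx)
  # radial angles relative to the axis seen from each trimer's own centre
  phi <- ang - ifelse(g1, u, u + pi)
  r <- mean(ri)
  psi <- .wrapAngle(.circMean(3 * phi) / 3) %% (2 * pi / 3)
  k <- round(((phi - psi) %% (2 * pi)) / (2 * pi / 3)) %% 3
  e1 <- .wrapAngle(.circMean(poses$theta - ang))
  params <- p6Params(rTrimer = r, dTrimers = d, psi = psi,
                     euler = c(e1, 0, 0))
  ideal <- p6GeneratePoses(params)
  idx <- ifelse(g1, 0L, 3L) + k + 1L   # matching ideal row for each pose
  Q <- cbind(ideal$x, ideal$y)[idx, , drop = FALSE]
  list(params = params, deviation = .rmsdRigid(P, Q))
}

# RMS distance between point sets after optimal rigid superposition
# (2D Kabsch: rotation, no reflection, plus translation).
.rmsdRigid <- function(P, Q) {
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  sv <- svd(t(Q0) %*% P0)
  s <- sign(det(sv$u %*% t(sv$v)))
  if (s == 0) s <- 1
  R <- sv$u %*% diag(c(1, s)) %*% t(sv$v)
  sqrt(mean(rowSums((P0 - Q0 %*% R)^2)))
}
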