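# Growth-law classification and coarsening exponents for largest-cluster
# time series.

# steady-state window: records after the initial filling phase (occupancy
# first exceeding plateauFraction of its final value) and strictly before
# the first percolation record.
.steadyWindow <- function(series, plateauFraction = 0.9) {
  stopifnot(is.data.frame(series), nrow(series) >= 1L)
  finalOcc <- series$n_occupied[nrow(series)]
  start <- which(series$n_occupied >= plateauFraction * finalOcc)[1L]
  firstPerc <- which(series$percolated > 0L)[1L]
  end <- if (is.na(firstPerc)) nrow(series) else firstPerc - 1L
  c(start = start, end = end)
}

.aicc <- function(ll, k, n) {
  aic <- -2 * ll + 2 * k
  if (n - k - 1 <= 0) return(Inf)
  aic + 2 * k * (k + 1) / (n - k - 1)
}

#' Classify largest-cluster growth as linear or exponential
#'
#' Fits size ~ sweep (linear) and log(size) ~ sweep (exponential) by least
#' squares on the steady-state window -- the records after the initial
#' filling phase (default: from where occupancy first exceeds 90 percent of
#' its final plateau) and before percolation (exclusive), where growth is
#' independent of the initial conditions and of finite-size effects. The
#' models are compared by corrected AIC on the same observation scale (the
#' exponential model's likelihood includes the Jacobian of the log
#' transform); a margin of 2 separates a call from "indeterminate".
#'
#' @param series a TimeSeries data.frame (see \code{\link{runSimulation}}).
#' @param plateauFraction occupancy fraction of the final value that ends
#'   the filling phase (default 0.9).
#' @param minPoints minimum records required in the window (default 10).
#' @return A \linkS4class{GrowthFit}.
#' @export
classifyGrowth <- function(series, plateauFraction = 0.9, minPoints = 10L) {
  win <- .steadyWindow(series, plateauFraction)
  empty <- new("GrowthFit", window = c(NA_real_, NA_real_),
               linearFit = c(NA_real_, NA_real_), linearSE = c(NA_real_, NA_real_),
               linearAICc = NA_real_, expFit = c(NA_real_, NA_real_),
               expAICc = NA_real_, label = "indeterminate", nPoints = 0L,
               note = "")
  if (is.na(win["start"]) || win["end"] < win["start"]) {
    empty@note <- "no steady-state window (percolation before plateau)"
    return(empty)
  }
  sub <- series[win["start"]:win["end"], ]
  sub <- sub[sub$largest_cluster > 0L, ]   # log model needs positive sizes
  n <- nrow(sub)
  if (n < minPoints) {
    empty@note <- sprintf("window too short (%d records, need %d)", n, minPoints)
    empty@nPoints <- as.integer(n)
    return(empty)
  }
  t <- sub$sweep
  y <- sub$largest_cluster
  flin <- lm(y ~ t)
  fexp <- lm(log(y) ~ t)
  aiccLin <- .aicc(as.numeric(logLik(flin)), 3L, n)
  # Jacobian of the log transform puts the log-scale likelihood on the
  # observation scale of y
  aiccExp <- .aicc(as.numeric(logLik(fexp)) - sum(log(y)), 3L, n)
  delta <- aiccLin - aiccExp
  label <- if (!is.finite(delta) || abs(delta) < 2) "indeterminate"
           else if (delta > 0) "exponential" else "linear"
  se <- suppressWarnings(summary(flin))$coefficients[, "Std. Error"]
  new("GrowthFit",
      window = c(sub$sweep[1L], sub$sweep[n]),
      linearFit = unname(coef(flin)), linearSE = unname(se),
      linearAICc = aiccLin,
      expFit = unname(coef(fexp)), expAICc = aiccExp,
      label = label, nPoints = as.integer(n), note = "")
}

#' Coarsening exponent of largest-cluster growth
#'
#' Slope of log(size) versus log(sweep) on the steady-state window. For
#' P6-only dynamics the model coarsens like a 2D seven-state Potts model:
#' domain radius ~ t^(1/2), i.e. largest-cluster area ~ t and an exponent
#' near 1.
#'
#' @inheritParams classifyGrowth
#' @param window optional integer vector c(start, end) of record indices;
#'   defaults to the steady-state window.
#' @return List with elements exponent, se, window (sweep range) and n.
#' @export
estimateCoarseningExponent <- function(series, plateauFraction = 0.9,
                                       window = NULL) {
  if (is.null(window)) {
    win <- .steadyWindow(series, plateauFraction)
    if (is.na(win["start"]) || win["end"] < win["start"])
      stop("no steady-state window available")
    window <- win["start"]:win["end"]
  }
  sub <- series[window, ]
  sub <- sub[sub$sweep > 0L, ]
  if (nrow(sub) < 5L) stop("need at least 5 records with positive sweep")
  if (any(sub$largest_cluster <= 0L))
    stop("nonpositive cluster sizes in the window")
  fit <- lm(log(largest_cluster) ~ log(sweep), data = sub)
  sm <- suppressWarnings(summary(fit))$coefficients
  list(exponent = unname(coef(fit)[2L]), se = unname(sm[2L, "Std. Error"]),
       window = range(sub$sweep), n = nrow(sub))
}
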