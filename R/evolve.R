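#' Integrate the master equation
#'
#' Solves `dp/dt = K(t) p` on the flat joint space from `ti` to `tf`.
#' For constant or piecewise-constant protocols the propagation uses
#' matrix exponentials per protocol segment (exact up to the matrix
#' exponential itself); arbitrary time-dependent rates fall back to a
#' dense stiff ODE solver ([deSolve::ode()], `lsoda`).  Snapshots are
#' stored on a time grid that refines the protocol segments; probability
#' is conserved to `1e-8` at every grid point (checked).
#'
#' Systems are desk-scale: a warning is issued above 20 000 joint states.
#'
#' @param sys a `composite_system`.
#' @param p0 initial `distribution` on `sys$space`.
#' @param ti,tf start and end times, `ti < tf`.
#' @param n_steps total number of grid steps (distributed over protocol
#'   segments proportionally to their length, minimum 8 per segment).
#' @param rtol,atol solver tolerances for the ODE fallback.
#' @return an object of class `evolution_record` with fields `times`
#'   (grid), `probs` (states x times matrix), `sys`, and `meta`.
#' @export
evolve <- function(sys, p0, ti, tf, n_steps = 200, rtol = 1e-8,
                   atol = 1e-12) {
  stopifnot(inherits(sys, "composite_system"),
            inherits(p0, "distribution"))
  if (!identical(p0$space$sizes, sys$space$sizes))
    stop("initial distribution lives on a different space")
  if (!(ti < tf)) stop("ti must be < tf")
  if (sys$space$n > 20000)
    warning("joint space has ", sys$space$n,
            " states; this is a desk-scale tool")
  segs <- protocol_segments(sys, ti, tf)
  piecewise <- all(vapply(sys$reservoirs, `[[`, "", "kind") %in%
                   c("constant", "piecewise"))
  times <- ti
  probs <- matrix(p0$p, ncol = 1)
  p <- p0$p
  steps_used <- 0L
  for (s in seq_len(nrow(segs))) {
    len <- segs$t1[s] - segs$t0[s]
    m <- max(8L, ceiling(n_steps * len / (tf - ti)))
    h <- len / m
    tmid <- segs$t0[s] + len / 2
    if (piecewise) {
      K <- global_rate(sys, tmid)
      P <- as.matrix(Matrix::expm(K * h))
      for (k in seq_len(m)) {
        p <- as.numeric(P %*% p)
        times <- c(times, segs$t0[s] + k * h)
        probs <- cbind(probs, p)
      }
    } else {
      grid <- segs$t0[s] + h * (0:m)
      deriv <- function(t, y, parms) list(as.numeric(global_rate(sys, t) %*% y))
      sol <- deSolve::ode(y = p, times = grid, func = deriv, parms = NULL,
                          method = "lsoda", rtol = rtol, atol = atol)
      p <- as.numeric(sol[nrow(sol), -1])
      times <- c(times, grid[-1])
      probs <- cbind(probs, t(unname(sol[-1, -1, drop = FALSE])))
    }
    steps_used <- steps_used + m
  }
  drift <- max(abs(colSums(probs) - 1))
  if (drift > 1e-8)
    stop("probability conservation violated (drift ", format(drift), ")")
  if (any(probs < -1e-8)) stop("negative probabilities in solution")
  probs[probs < 0] <- 0
  structure(
    list(times = times, probs = unname(probs), sys = sys,
         meta = list(method = if (piecewise) "expm" else "lsoda",
                     n_steps = steps_used, rtol = rtol,
                     max_norm_drift = drift)),
    class = "evolution_record")
}

# Split [ti, tf] at the protocol breakpoints.
protocol_segments <- function(sys, ti, tf) {
  br <- sys$breaks
  cuts <- sort(unique(c(ti, tf, br[br > ti + 1e-12 & br < tf - 1e-12])))
  data.frame(t0 = utils::head(cuts, -1), t1 = utils::tail(cuts, -1))
}

#' @export
print.evolution_record <- function(x, ...) {
  cat("<evolution_record> ", length(x$times), " snapshots on [",
      x$times[1], ", ", x$times[length(x$times)], "], method ",
      x$meta$method, "\n", sep = "")
  invisible(x)
}

#' Distribution snapshot at a recorded grid point
#' @param record an `evolution_record`.
#' @param t time; must coincide (within `1e-9`) with a grid point.
#' @export
snapshot <- function(record, t) {
  k <- which.min(abs(record$times - t))
  if (abs(record$times[k] - t) > 1e-9 * max(1, abs(t)))
    stop("t is not on the recorded grid")
  distribution(record$sys$space, record$probs[, k], normalize = TRUE)
}

#' Final distribution of a record
#' @param record an `evolution_record`.
#' @export
final_distribution <- function(record) {
  distribution(record$sys$space, record$probs[, ncol(record$probs)],
               normalize = TRUE)
}

#' Export an evolution record as CSV
#'
#' Columns: `t`, then one probability column per joint state label.
#'
#' @param record an `evolution_record`.
#' @param path file path.
#' @export
write_record_csv <- function(record, path) {
  df <- data.frame(t = record$times, t(record$probs),
                   check.names = FALSE)
  names(df) <- c("t", state_labels(record$sys$space))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Conditional map implemented by a system over a time window
#'
#' Column `j` of the result is the solution of the master equation from
#' the point mass on flat state `j`; for piecewise-constant protocols the
#' whole propagator is a product of segment matrix exponentials.
#'
#' @inheritParams evolve
#' @return a `stochastic_map`.
#' @export
conditional_map <- function(sys, ti, tf, n_steps = 200, rtol = 1e-8) {
  segs <- protocol_segments(sys, ti, tf)
  piecewise <- all(vapply(sys$reservoirs, `[[`, "", "kind") %in%
                   c("constant", "piecewise"))
  n <- sys$space$n
  if (piecewise) {
    U <- diag(n)
    for (s in seq_len(nrow(segs))) {
      len <- segs$t1[s] - segs$t0[s]
      K <- global_rate(sys, segs$t0[s] + len / 2)
      U <- as.matrix(Matrix::expm(K * len)) %*% U
    }
  } else {
    U <- matrix(0, n, n)
    for (j in seq_len(n)) {
      p0 <- distribution(sys$space, as.numeric(seq_len(n) == j))
      rec <- evolve(sys, p0, ti, tf, n_steps = n_steps, rtol = rtol)
      U[, j] <- rec$probs[, ncol(rec$probs)]
    }
  }
  U[U < 0] <- 0
  U <- sweep(U, 2, colSums(U), `/`)
  stochastic_map(sys$space, U)
}

#' Necessary consistency of a conditional map with a unit structure
#'
#' For every unit, the marginal conditional `p(x_omega(tf) | x(ti))` must
#' be independent of the initial states outside the unit.  This is a
#' necessary condition for the map to be implementable by a rate matrix
#' obeying the structure, not a sufficient one; results are flagged
#' accordingly.
#'
#' @param map a `stochastic_map`.
#' @param nstar a `unit_structure` over the map's coordinates.
#' @param tol tolerance on the independence check.
#' @return logical; attributes `max_residual`, `witness` (on failure) and
#'   `necessary_conditions_only = TRUE`.
#' @export
conditional_consistency_check <- function(map, nstar, tol = 1e-8) {
  space <- map$space
  worst <- 0; witness <- NULL
  for (u in nstar$units) {
    midx <- marginal_index(space, u)
    Mu <- rowsum(map$matrix, midx, reorder = TRUE)
    srcu <- midx
    for (g in unique(srcu)) {
      cols <- which(srcu == g)
      if (length(cols) < 2) next
      dev <- abs(Mu[, cols, drop = FALSE] - Mu[, cols[1]])
      d <- max(dev)
      if (d > worst) {
        worst <- d
        witness <- list(unit = u, source_a = cols[1],
                        source_b = cols[which(dev == d, arr.ind = TRUE)[1, 2]])
      }
    }
  }
  structure(worst <= tol, max_residual = worst, witness = witness,
            necessary_conditions_only = TRUE)
}
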