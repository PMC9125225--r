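# Entropy-flow and entropy-production functionals.
#
# All quantities are in nats (kB = 1); rates are nats per unit time.
# Entry convention follows the master equation dp/dt = K p: the rate
# from x' to x is K[x, x'].

# Per-reservoir transition tables (forward/reverse local entries) at time
# t, as parallel vectors over all off-diagonal embedded transitions.
reservoir_transitions <- function(sys, vname, t) {
  emb <- sys$embeddings[[vname]]
  M <- reservoir_rates(sys$reservoirs[[vname]], t)
  nP <- nrow(emb$G); n <- ncol(emb$G)
  src <- rep(seq_len(n), each = nP)          # global source index
  dst <- as.vector(emb$G)                    # global destination index
  off <- dst != src
  src <- src[off]; dst <- dst[off]
  fwd <- M[cbind(rep(seq_len(nP), n)[off], emb$lidx[src])]
  rev <- M[cbind(emb$pidx[src], emb$lidx[dst])]
  list(src = src, dst = dst, fwd = fwd, rev = rev)
}

check_weak_reversibility <- function(tr, vname) {
  bad <- which(tr$fwd > 0 & tr$rev <= 0)
  if (length(bad))
    stop("irreversible transition in reservoir ", vname, ": rate ",
         tr$src[bad[1]], " -> ", tr$dst[bad[1]],
         " is positive but its reverse vanishes (log-ratio undefined)")
}

reservoir_ef <- function(sys, vname, p, t) {
  tr <- reservoir_transitions(sys, vname, t)
  check_weak_reversibility(tr, vname)
  act <- tr$fwd > 0 & p[tr$src] > 0
  sum(tr$fwd[act] * p[tr$src[act]] * log(tr$fwd[act] / tr$rev[act]))
}

reservoir_ep <- function(sys, vname, p, t) {
  tr <- reservoir_transitions(sys, vname, t)
  check_weak_reversibility(tr, vname)
  act <- tr$fwd > 0 & p[tr$src] > 0
  num <- tr$fwd[act] * p[tr$src[act]]
  den <- tr$rev[act] * p[tr$dst[act]]
  sum(num * log(num / den))   # +Inf if a target state has zero mass
}

#' Restriction of a system to a unit with all its reservoirs inside
#'
#' Requires every reservoir affecting `omega` to have its leader set
#' inside `omega` (the tightness condition for this unit); the restricted
#' system's global rate matrix is then the unit's own generator.
#'
#' @param sys a `composite_system`.
#' @param omega character vector of coordinate names.
#' @export
unit_system <- function(sys, omega) {
  omega <- check_coord_names(sys$space, omega)
  vs <- reservoirs_affecting(sys, omega)
  for (v in vs)
    if (!all(sys$reservoirs[[v]]$leaders %in% omega))
      stop("reservoir ", v, " reaches outside {",
           paste(omega, collapse = ","),
           "}; the unit is not tight, its own generator is unavailable")
  composite_system(subspace(sys$space, omega), sys$reservoirs[vs],
                   allow_duplicate_puppets = TRUE, t_range = sys$t_range)
}

resolve_scope <- function(sys, scope) {
  if (identical(scope, "global")) return(names(sys$reservoirs))
  reservoirs_affecting(sys, scope)
}

#' Entropy-flow rate into the reservoirs, in nats per time
#'
#' The global scope sums `L[x,x'] p[x'] log(L[x,x']/L[x',x])` over every
#' reservoir and transition; a unit scope restricts the sum to the
#' reservoirs affecting the unit, and a difference scope
#' `list(omega, omega_prime)` (with `omega_prime` inside `omega`) returns
#' the signed-measure extension, the difference of the two unit rates.
#' Transitions with a positive forward rate but vanishing reverse rate
#' are rejected (the log-ratio is undefined).
#'
#' @param sys a `composite_system`.
#' @param p a `distribution` on the system's space.
#' @param t time.
#' @param scope `"global"`, a character vector naming a unit, or a list
#'   of two such vectors for a unit difference.
#' @param check verify that unit scopes pass [is_unit()] (skip in tight
#'   loops).
#' @export
ef_rate <- function(sys, p, t = 0, scope = "global", check = TRUE) {
  if (is.list(scope)) {
    stopifnot(length(scope) == 2, all(scope[[2]] %in% scope[[1]]))
    return(ef_rate(sys, p, t, scope[[1]], check) -
           ef_rate(sys, p, t, scope[[2]], check))
  }
  if (!identical(scope, "global") && check &&
      !is_unit(sys, scope, times = t))
    stop("scope {", paste(scope, collapse = ","), "} is not a unit at t = ", t)
  sum(vapply(resolve_scope(sys, scope),
             function(v) reservoir_ef(sys, v, p$p, t), numeric(1)))
}

#' Entropy-production rate, in nats per time
#'
#' Global scope: the Schnakenberg sum
#' `sum L[x,x'] p[x'] log( L[x,x'] p[x'] / (L[x',x] p[x]) )` over all
#' reservoirs; non-negative by the log-sum inequality.  A unit scope
#' evaluates the same sum on the unit's own restricted system (which
#' requires the unit to be tight) with the unit's marginal distribution.
#' If mass sits on a state whose reverse-transition target has zero mass
#' the instantaneous rate is `+Inf`.
#'
#' @inheritParams ef_rate
#' @export
ep_rate <- function(sys, p, t = 0, scope = "global", check = TRUE) {
  if (identical(scope, "global"))
    return(sum(vapply(names(sys$reservoirs),
                      function(v) reservoir_ep(sys, v, p$p, t), numeric(1))))
  if (check && !is_unit(sys, scope, times = t))
    stop("scope {", paste(scope, collapse = ","), "} is not a unit at t = ", t)
  usys <- unit_system(sys, scope)   # errors when not tight
  pu <- marginalize(p, scope)
  sum(vapply(names(usys$reservoirs),
             function(v) reservoir_ep(usys, v, pu$p, t), numeric(1)))
}

#' Time derivative of the joint Shannon entropy
#' @inheritParams ef_rate
#' @export
entropy_rate <- function(sys, p, t = 0) {
  K <- global_rate(sys, t)
  dp <- as.numeric(K %*% p$p)
  pos <- p$p > 0
  if (any(abs(dp[!pos]) > 0)) {
    # mass flowing into empty states: -dp*log p diverges; report +Inf
    if (any(dp[!pos] > 1e-300)) return(Inf)
  }
  -sum(dp[pos] * log(p$p[pos]))
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) +
                                       utils::tail(y, -1)) / 2)

# Composite trapezoid with one Richardson refinement pass: the value is
# extrapolated from the full and half-resolution grids, and the error is
# estimated by comparing against the extrapolation of the half and
# quarter grids.
trapz_refined <- function(x, y) {
  q1 <- trapz(x, y)
  i2 <- unique(c(seq(1, length(x), by = 2), length(x)))
  q2 <- trapz(x[i2], y[i2])
  i4 <- unique(c(seq(1, length(x), by = 4), length(x)))
  q4 <- trapz(x[i4], y[i4])
  v <- q1 + (q1 - q2) / 3
  vc <- q2 + (q2 - q4) / 3
  list(value = v, error = abs(v - vc))
}

# EF rate of one reservoir for a block of probability columns, all
# evaluated with the rates at time t_eval.
reservoir_ef_block <- function(sys, vname, probs, t_eval) {
  tr <- reservoir_transitions(sys, vname, t_eval)
  check_weak_reversibility(tr, vname)
  act <- tr$fwd > 0
  if (!any(act)) return(numeric(ncol(probs)))
  w <- tr$fwd[act] * log(tr$fwd[act] / tr$rev[act])
  as.numeric(crossprod(probs[tr$src[act], , drop = FALSE], w))
}

#' Integrated thermodynamic report for a unit structure
#'
#' Integrates the entropy-flow rate of every reservoir over the record's
#' time grid (composite trapezoid with a half-grid error estimate) and
#' assembles, per unit and globally: integrated entropy flow `Q`,
#' integrated entropy production `sigma = Delta S + Q` (endpoint
#' entropies are taken from the recorded snapshots, so no
#' entropy-derivative quadrature is needed), the in-ex information at
#' both endpoints, the strengthened-second-law bound `B`, the
#' decomposition residuals, and the inequality checks.
#'
#' @param sys a `composite_system` (must be the record's system).
#' @param record an `evolution_record` from [evolve()].
#' @param nstar a validated `unit_structure`.
#' @param tol quadrature tolerance on integrated quantities.
#' @return an object of class `thermo_report`.
#' @export
integrate_thermo <- function(sys, record, nstar, tol = 1e-6) {
  stopifnot(inherits(record, "evolution_record"),
            identical(sys$space$sizes, record$sys$space$sizes))
  times <- record$times
  nT <- length(times)
  vs <- names(sys$reservoirs)
  piecewise <- all(vapply(sys$reservoirs, `[[`, "", "kind") %in%
                   c("constant", "piecewise"))
  segs <- protocol_segments(sys, times[1], times[nT])
  # quadrature segment by segment: the EF integrand may jump at protocol
  # breakpoints, where the grid carries both one-sided values
  ef_series <- matrix(0, length(vs), nT, dimnames = list(vs, NULL))
  Qv <- numeric(length(vs)); names(Qv) <- vs
  qerr <- 0
  for (s in seq_len(nrow(segs))) {
    i0 <- which.min(abs(times - segs$t0[s]))
    i1 <- which.min(abs(times - segs$t1[s]))
    idx <- i0:i1
    for (v in vs) {
      # piecewise-constant rates: one evaluation per segment (midpoint);
      # callable rates: pointwise
      if (piecewise || sys$reservoirs[[v]]$kind != "callable") {
        y <- reservoir_ef_block(sys, v, record$probs[, idx, drop = FALSE],
                                (segs$t0[s] + segs$t1[s]) / 2)
      } else {
        y <- vapply(idx, function(k) reservoir_ef(sys, v,
                                                  record$probs[, k],
                                                  times[k]), numeric(1))
      }
      ef_series[v, idx] <- y
      r <- trapz_refined(times[idx], y)
      Qv[v] <- Qv[v] + r$value; qerr <- qerr + r$error
    }
  }
  if (qerr > tol)
    stop("quadrature error estimate ", format(qerr),
         " exceeds tol = ", tol,
         "; re-run evolve() with more n_steps")
  p_i <- snapshot(record, times[1])
  p_f <- final_distribution(record)

  S_i <- function(u) marginal_entropy(p_i, u)
  S_f <- function(u) marginal_entropy(p_f, u)
  Q_of <- function(u) sum(Qv[reservoirs_affecting(sys, u)])
  sigma_of <- function(u) (S_f(u) - S_i(u)) + Q_of(u)

  lab <- vapply(nstar$units, paste, "", collapse = ",")
  Q_units <- stats::setNames(vapply(nstar$units, Q_of, numeric(1)), lab)
  sigma_units <- stats::setNames(vapply(nstar$units, sigma_of, numeric(1)),
                                 lab)
  Q_N <- sum(Qv)
  sigma_N <- (shannon_entropy(p_f) - shannon_entropy(p_i)) + Q_N

  I_i <- in_ex_information(p_i, nstar)
  I_f <- in_ex_information(p_f, nstar)
  B <- I_i - I_f

  # pointwise EF decomposition residual: the in-ex sum counts reservoir v
  # with multiplicity c_v, which must be 1 for every reservoir
  cv <- vapply(vs, function(v) inclusion_exclusion_sum(
    function(u) as.numeric(v %in% reservoirs_affecting(sys, u)), nstar),
    numeric(1))
  ef_resid_series <- as.numeric(t(1 - cv) %*% ef_series)
  ef_residual <- max(abs(ef_resid_series))

  inex_sigma <- inclusion_exclusion_sum(sigma_of, nstar)
  ep_residual <- sigma_N - (inex_sigma - (I_f - I_i))

  height <- graph_height(nstar)
  checks <- c(
    sigma_global_nonneg = sigma_N >= -tol,
    sigma_units_nonneg = all(sigma_units >= -tol),
    sigma_ge_bound = sigma_N >= B - tol,
    ef_decomposition = ef_residual < 1e-8,
    ep_decomposition = abs(ep_residual) < 1e-5)

  structure(
    list(Q = Q_units, sigma = sigma_units, Q_N = Q_N, sigma_N = sigma_N,
         Q_reservoirs = Qv,
         I_initial = I_i, I_final = I_f, B = B,
         residuals = list(ef_pointwise = ef_residual,
                          ep_integrated = ep_residual,
                          quadrature = qerr),
         checks = checks,
         height = height,
         bound_guaranteed = height <= 2,
         nstar = nstar, p_initial = p_i, p_final = p_f,
         sigma_of = sigma_of, S_i = S_i, S_f = S_f),
    class = "thermo_report")
}

#' @export
print.thermo_report <- function(x, ...) {
  cat("<thermo_report>\n")
  cat("  sigma_N =", format(x$sigma_N, digits = 6),
      "  Q_N =", format(x$Q_N, digits = 6), "\n")
  cat("  I(ti) =", format(x$I_initial, digits = 6),
      "  I(tf) =", format(x$I_final, digits = 6),
      "  B =", format(x$B, digits = 6),
      if (!x$bound_guaranteed) " [height > 2: bound not guaranteed]",
      "\n")
  for (u in names(x$sigma))
    cat(sprintf("  sigma{%s} = %s\n", u, format(x$sigma[u], digits = 6)))
  cat("  checks:", paste(names(x$checks)[x$checks], collapse = ", "), "\n")
  bad <- names(x$checks)[!x$checks]
  if (length(bad)) cat("  FAILED:", paste(bad, collapse = ", "), "\n")
  invisible(x)
}

#' Strengthened second-law lower bound on entropy production
#'
#' `B = I(p_i) - I(p_f)` in nats, where `I` is the in-ex information of
#' the unit structure.  The bound `sigma_N >= B` is guaranteed for
#' dependency graphs of height at most 2; for taller structures the value
#' is still returned but carries attribute `guaranteed = FALSE`.  `B`
#' depends only on the endpoint distributions, never on the dynamics, and
#' can be negative.
#'
#' @param p_i,p_f endpoint `distribution`s over the structure's
#'   coordinates.
#' @param nstar a `unit_structure`.
#' @export
ssl_bound <- function(p_i, p_f, nstar) {
  B <- in_ex_information(p_i, nstar) - in_ex_information(p_f, nstar)
  h <- graph_height(nstar)
  attr(B, "height") <- h
  attr(B, "guaranteed") <- h <= 2
  B
}

#' Root-node entropy-drop bound
#'
#' For processes in which every coordinate shared by two or more units
#' stays constant (or, more generally, the leaf-unit entropies return to
#' their starting values), the strengthened bound reduces to a sum over
#' the root units:
#' `B = sum_roots [S_w(ti) - S_w(tf)] - [S(ti) - S(tf)]`.
#' For disjoint singleton units this is the drop in multi-information.
#'
#' @inheritParams ssl_bound
#' @export
example1_bound <- function(p_i, p_f, nstar) {
  rt <- roots(nstar)
  sum(vapply(rt, function(u)
    marginal_entropy(p_i, u) - marginal_entropy(p_f, u), numeric(1))) -
    (shannon_entropy(p_i) - shannon_entropy(p_f))
}

#' Check the entropy-production inequalities of a report
#'
#' Evaluates, with slack recorded for each instance:
#' nested-unit monotonicity (`sigma_w >= sigma_a` for `a` inside `w`),
#' the disjoint-sum bound (`sigma_w >=` the sum over pairwise-disjoint
#' subunits), the sub-structure bound
#' (`sigma_w - inex-sum of sigma over the proper subunits >= I_i - I_f`
#' of that sub-structure), global and per-unit non-negativity, and
#' `sigma_N >= B`.
#'
#' @param report a `thermo_report`.
#' @param tol violation tolerance.
#' @return list with `all_ok`, and a data frame `details` of every
#'   inequality instance and its slack.
#' @export
check_inequalities <- function(report, tol = 1e-6) {
  units <- report$nstar$units
  lab <- vapply(units, paste, "", collapse = ",")
  rows <- list()
  add <- function(kind, what, slack)
    rows[[length(rows) + 1]] <<- data.frame(kind = kind, instance = what,
                                            slack = slack)
  add("second_law", "N", report$sigma_N)
  for (i in seq_along(units))
    add("second_law", lab[i], report$sigma[lab[i]])
  add("ssl", "N", report$sigma_N - report$B)
  for (i in seq_along(units)) for (j in seq_along(units)) {
    if (i == j) next
    if (all(units[[i]] %in% units[[j]]) &&
        length(units[[i]]) < length(units[[j]]))
      add("nested", paste0(lab[j], " >= ", lab[i]),
          report$sigma[lab[j]] - report$sigma[lab[i]])
  }
  for (j in seq_along(units)) {
    subs <- which(vapply(units, function(u)
      all(u %in% units[[j]]) && length(u) < length(units[[j]]), logical(1)))
    if (!length(subs)) next
    # maximal pairwise-disjoint subfamily, greedy by size
    ord <- subs[order(-lengths(units[subs]))]
    fam <- integer(0)
    for (k in ord)
      if (!length(fam) ||
          !length(intersect(units[[k]], unlist(units[fam]))))
        fam <- c(fam, k)
    add("disjoint_sum", paste0(lab[j], " >= sum(",
                               paste(lab[fam], collapse = " + "), ")"),
        report$sigma[lab[j]] - sum(report$sigma[lab[fam]]))
    # sub-structure bound over all proper subunits
    mstar <- unit_structure(units[subs], allow_full = TRUE, check = FALSE)
    inex_sub <- inclusion_exclusion_sum(report$sigma_of, mstar)
    bound_sub <- in_ex_information(report$p_initial, mstar) -
      in_ex_information(report$p_final, mstar)
    add("substructure", lab[j],
        (report$sigma[lab[j]] - inex_sub) - bound_sub)
  }
  details <- do.call(rbind, rows)
  rownames(details) <- NULL
  list(all_ok = all(details$slack >= -tol), details = details)
}

#' Serialize a thermodynamic report as JSON
#'
#' Keys: `Q` and `sigma` (unit-label maps), `Q_N`, `sigma_N`,
#' `I_initial`, `I_final`, `B`, `residuals`, `checks`, `height`,
#' `bound_guaranteed`.
#'
#' @param report a `thermo_report`.
#' @param path file path.
#' @export
write_report_json <- function(report, path) {
  obj <- list(
    Q = as.list(report$Q), sigma = as.list(report$sigma),
    Q_N = report$Q_N, sigma_N = report$sigma_N,
    I_initial = report$I_initial, I_final = report$I_final,
    B = report$B, residuals = report$residuals,
    checks = as.list(report$checks),
    height = report$height, bound_guaranteed = report$bound_guaranteed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export EF/EP rate time series as CSV
#'
#' Columns `t`, `scope`, `ef_rate`, `ep_rate`; one block per scope
#' (`global` plus each unit).  Unit EP rates require tightness and are
#' `NA` where unavailable.
#'
#' @param sys a `composite_system`.
#' @param record an `evolution_record`.
#' @param nstar a `unit_structure`.
#' @param path file path.
#' @export
write_rate_series_csv <- function(sys, record, nstar, path) {
  scopes <- c(list("global"), nstar$units)
  labs <- c("global", vapply(nstar$units, paste, "", collapse = ","))
  out <- list()
  for (s in seq_along(scopes)) {
    ef <- ep <- rep(NA_real_, length(record$times))
    for (k in seq_along(record$times)) {
      p <- distribution(sys$space, record$probs[, k], normalize = TRUE)
      ef[k] <- ef_rate(sys, p, record$times[k], scopes[[s]], check = FALSE)
      ep[k] <- tryCatch(
        ep_rate(sys, p, record$times[k], scopes[[s]], check = FALSE),
        error = function(e) NA_real_)
    }
    out[[s]] <- data.frame(t = record$times, scope = labs[s],
                           ef_rate = ef, ep_rate = ep)
  }
  utils::write.csv(do.call(rbind, out), path, row.names = FALSE)
  invisible(path)
}
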