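#' Reservoir coupled to a subset of coordinates
#'
#' A reservoir `v` drives fluctuations of the coordinates in its *puppet
#' set* `P(v)` and leaves every other coordinate untouched.  Its rate
#' entries may depend on the source state only through the coordinates of
#' its *leader set* `L(v) >= P(v)`.  Rates are given as a local matrix with
#' one row per destination puppet-substate and one column per source
#' leader-substate (both in the flat enumeration of the respective
#' sub-spaces); each column sums to zero, with the negative escape entry
#' sitting at the row matching the puppet part of the source.
#'
#' `rates` may be (a) a constant matrix, (b) a piecewise-constant protocol
#' given as a list of segments `list(t0 =, t1 =, rates = <matrix>)`, or
#' (c) an arbitrary function `t -> matrix`.  Alternatively a full matrix
#' over the joint space may be supplied (`validate_reservoir()` then checks
#' that it really only moves puppets and only reads leaders).
#'
#' @param name reservoir label.
#' @param puppets character vector of puppet coordinate names.
#' @param leaders character vector of leader coordinate names (must contain
#'   the puppets).
#' @param rates rate specification, see Details.
#' @return an object of class `reservoir`.
#' @export
reservoir <- function(name, puppets, leaders, rates) {
  if (!all(puppets %in% leaders))
    stop("puppet set must be contained in leader set")
  kind <-
    if (is.matrix(rates)) "constant"
    else if (is.function(rates)) "callable"
    else if (is.list(rates)) "piecewise"
    else stop("unsupported rates specification")
  if (kind == "piecewise") {
    t0 <- vapply(rates, `[[`, numeric(1), "t0")
    t1 <- vapply(rates, `[[`, numeric(1), "t1")
    o <- order(t0)
    rates <- rates[o]; t0 <- t0[o]; t1 <- t1[o]
    if (any(t1 <= t0) || any(utils::head(t1, -1) > utils::tail(t0, -1) + 1e-12))
      stop("piecewise segments must be increasing and non-overlapping")
  }
  structure(
    list(name = name, puppets = as.character(puppets),
         leaders = as.character(leaders), rates = rates, kind = kind),
    class = "reservoir")
}

#' @export
print.reservoir <- function(x, ...) {
  cat("<reservoir> ", x$name, ": puppets {",
      paste(x$puppets, collapse = ","), "}, leaders {",
      paste(x$leaders, collapse = ","), "}, ", x$kind, " rates\n", sep = "")
  invisible(x)
}

#' Breakpoints of a reservoir's protocol (empty for constant rates)
#' @param r a `reservoir`.
#' @export
reservoir_breaks <- function(r) {
  if (r$kind != "piecewise") return(numeric(0))
  sort(unique(c(vapply(r$rates, `[[`, numeric(1), "t0"),
                vapply(r$rates, `[[`, numeric(1), "t1"))))
}

#' Local rate matrix of a reservoir at time t
#'
#' Segments are half-open `[t0, t1)`; the final segment also covers its
#' right endpoint.
#'
#' @param r a `reservoir`.
#' @param t time.
#' @export
reservoir_rates <- function(r, t) {
  switch(r$kind,
    constant = r$rates,
    callable = r$rates(t),
    piecewise = {
      t0 <- vapply(r$rates, `[[`, numeric(1), "t0")
      t1 <- vapply(r$rates, `[[`, numeric(1), "t1")
      k <- which(t >= t0 - 1e-12 & (t < t1 | (t <= t1 + 1e-12 &
                                              seq_along(t1) == length(t1))))
      if (!length(k)) stop("time ", t, " outside protocol of reservoir ",
                           r$name)
      r$rates[[max(k)]]$rates
    })
}

# Flat-index offsets contributed by each puppet substate (0-based
# contribution to the global index).
puppet_offsets <- function(space, psub) {
  st <- all_states(psub)
  as.integer(st %*% space$strides[psub$names])
}

#' Validate a reservoir against a joint space
#'
#' Checks, at each sampled time: puppet/leader containment; that a
#' full-form matrix only moves puppet coordinates and depends on the
#' source only through the leaders; non-negative off-diagonal entries; and
#' zero column sums (tolerance `1e-10`).  Violations are returned (one
#' character string each, with witnesses), never raised.
#'
#' @param r a `reservoir`.
#' @param space the `joint_space` the reservoir acts on.
#' @param times numeric vector of protocol times to sample.
#' @return character vector of violations; empty if the reservoir is valid.
#' @export
validate_reservoir <- function(r, space, times = 0) {
  out <- character(0)
  bad <- setdiff(c(r$puppets, r$leaders), space$names)
  if (length(bad))
    return(paste0("unknown coordinate(s): ", paste(bad, collapse = ",")))
  if (!all(r$puppets %in% r$leaders))
    out <- c(out, "puppet set not contained in leader set")
  psub <- subspace(space, r$puppets); lsub <- subspace(space, r$leaders)
  for (t in times) {
    M <- reservoir_rates(r, t)
    if (all(dim(M) == c(space$n, space$n)) &&
        !(psub$n == space$n && lsub$n == space$n)) {
      out <- c(out, validate_full_matrix(r, space, M, t))
      next
    }
    if (!all(dim(M) == c(psub$n, lsub$n))) {
      out <- c(out, sprintf(
        "t=%g: rate matrix is %dx%d, expected %dx%d (puppet x leader)",
        t, nrow(M), ncol(M), psub$n, lsub$n))
      next
    }
    prow <- puppet_row_of_leader(space, r)
    # row prow[c] is the escape (diagonal) entry of column c
    is_diag <- as.vector(outer(seq_len(psub$n), prow, `==`))
    if (any(as.vector(M)[!is_diag] < -1e-10))
      out <- c(out, sprintf("t=%g: negative off-diagonal rate", t))
    cs <- colSums(M)
    if (any(abs(cs) > 1e-10))
      out <- c(out, sprintf(
        "t=%g: column sums not zero (max |sum| = %.3g at leader state %d)",
        t, max(abs(cs)), which.max(abs(cs))))
  }
  out
}

# Puppet-substate row index corresponding to each leader-substate column.
puppet_row_of_leader <- function(space, r) {
  psub <- subspace(space, r$puppets); lsub <- subspace(space, r$leaders)
  st <- all_states(lsub)[, psub$names, drop = FALSE]
  state_index(psub, st)
}

validate_full_matrix <- function(r, space, M, t) {
  out <- character(0)
  n <- space$n
  st <- all_states(space)
  notP <- setdiff(space$names, r$puppets)
  pidx <- marginal_index(space, r$puppets)
  lidx <- marginal_index(space, r$leaders)
  nz <- which(abs(M) > 1e-14, arr.ind = TRUE)
  nz <- nz[nz[, 1] != nz[, 2], , drop = FALSE]
  if (length(notP)) {
    moved <- which(vapply(seq_len(nrow(nz)), function(k) {
      any(st[nz[k, 1], notP] != st[nz[k, 2], notP])
    }, logical(1)))
    if (length(moved))
      out <- c(out, sprintf(
        "t=%g: moves non-puppet coordinate (e.g. transition %d -> %d)",
        t, nz[moved[1], 2], nz[moved[1], 1]))
  }
  # leader dependence: columns with equal leader substate must induce the
  # same puppet-jump rates
  key <- split(seq_len(n), lidx)
  poffs <- puppet_offsets(space, subspace(space, r$puppets))
  for (grp in key) {
    if (length(grp) < 2) next
    ref <- NULL
    for (j in grp) {
      base <- j - poffs[pidx[j]]
      col <- M[base + poffs, j]
      if (is.null(ref)) ref <- col
      else if (max(abs(col - ref)) > 1e-10) {
        out <- c(out, sprintf(
          "t=%g: non-leader dependence (source states %d vs %d)",
          t, grp[1], j))
        break
      }
    }
  }
  cs <- colSums(M)
  if (any(abs(cs) > 1e-10))
    out <- c(out, sprintf("t=%g: column sums not zero (max %.3g)",
                          t, max(abs(cs))))
  if (any(M[row(M) != col(M)] < -1e-10))
    out <- c(out, sprintf("t=%g: negative off-diagonal rate", t))
  out
}

#' Composite system: a joint space plus its reservoirs
#'
#' The union of all puppet sets must cover the coordinates, and no two
#' reservoirs may share an identical puppet set (the puppet-set map is
#' assumed invertible) unless `allow_duplicate_puppets = TRUE`.
#'
#' @param space a `joint_space`.
#' @param reservoirs list of `reservoir` objects.
#' @param allow_duplicate_puppets permit reservoirs with identical puppet
#'   sets.
#' @param t_range default protocol window used when sampling structural
#'   checks; inferred from piecewise protocols when possible.
#' @return an object of class `composite_system`.
#' @export
composite_system <- function(space, reservoirs,
                             allow_duplicate_puppets = FALSE,
                             t_range = NULL) {
  names(reservoirs) <- vapply(reservoirs, `[[`, character(1), "name")
  if (anyDuplicated(names(reservoirs))) stop("duplicate reservoir names")
  cover <- unique(unlist(lapply(reservoirs, `[[`, "puppets")))
  if (!setequal(intersect(cover, space$names), space$names) ||
      length(setdiff(cover, space$names)))
    stop("puppet sets must exactly cover the coordinates of the space")
  keys <- vapply(reservoirs,
                 function(r) paste(sort(r$puppets), collapse = ","), "")
  if (anyDuplicated(keys) && !allow_duplicate_puppets)
    stop("two reservoirs share a puppet set; pass ",
         "allow_duplicate_puppets = TRUE to permit this")
  breaks <- sort(unique(unlist(lapply(reservoirs, reservoir_breaks))))
  if (is.null(t_range))
    t_range <- if (length(breaks)) range(breaks) else c(0, 1)
  sys <- structure(
    list(space = space, reservoirs = reservoirs, breaks = breaks,
         t_range = t_range),
    class = "composite_system")
  sys$embeddings <- lapply(reservoirs, build_embedding, space = space)
  sys
}

#' @export
print.composite_system <- function(x, ...) {
  cat("<composite_system> ", x$space$n, " states, ",
      length(x$reservoirs), " reservoirs: ",
      paste(names(x$reservoirs), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Precomputed index tables embedding a reservoir's local matrix into the
# global rate matrix.
build_embedding <- function(r, space) {
  psub <- subspace(space, r$puppets); lsub <- subspace(space, r$leaders)
  pidx <- marginal_index(space, r$puppets)  # puppet substate of each state
  lidx <- marginal_index(space, r$leaders)  # leader substate of each state
  poffs <- puppet_offsets(space, psub)
  base <- seq_len(space$n) - poffs[pidx]
  G <- outer(poffs, base, `+`)              # G[r, j]: dest of j with puppet r
  list(psub = psub, lsub = lsub, pidx = pidx, lidx = lidx, G = G)
}

#' Reservoirs affecting a coordinate set, and leader/puppet closures
#'
#' `reservoirs_affecting()` returns nu(A): the names of every reservoir
#' whose puppet set meets `A`.  `leader_closure()` is `L(A)` (the union of
#' `A` with the leader sets of those reservoirs) and `puppet_closure()` is
#' `P(A)`; `A <= P(A) <= L(A)` always holds.
#'
#' @param sys a `composite_system`.
#' @param A character vector of coordinate names.
#' @export
reservoirs_affecting <- function(sys, A) {
  A <- check_coord_names(sys$space, A)
  hits <- vapply(sys$reservoirs,
                 function(r) length(intersect(r$puppets, A)) > 0, logical(1))
  names(sys$reservoirs)[hits]
}

#' @rdname reservoirs_affecting
#' @export
leader_closure <- function(sys, A) {
  A <- check_coord_names(sys$space, A)
  v <- reservoirs_affecting(sys, A)
  nm <- union(A, unlist(lapply(sys$reservoirs[v], `[[`, "leaders")))
  sys$space$names[sys$space$names %in% nm]
}

#' @rdname reservoirs_affecting
#' @export
puppet_closure <- function(sys, A) {
  A <- check_coord_names(sys$space, A)
  v <- reservoirs_affecting(sys, A)
  nm <- union(A, unlist(lapply(sys$reservoirs[v], `[[`, "puppets")))
  sys$space$names[sys$space$names %in% nm]
}

#' Global rate matrix at time t
#'
#' Assembles `K(t)` as the sum of every reservoir's embedded rate matrix.
#' Entry convention: `K[x, x']` is the rate *from* `x'` *to* `x` (sources
#' are columns), so the master equation reads `dp/dt = K %*% p`.  Columns
#' sum to zero and off-diagonal entries are non-negative.
#'
#' @param sys a `composite_system`.
#' @param t time.
#' @param validate recheck reservoir structure at `t` before assembling.
#' @return dense `n x n` matrix in the flat enumeration.
#' @export
global_rate <- function(sys, t = 0, validate = FALSE) {
  if (validate) {
    v <- unlist(lapply(sys$reservoirs, validate_reservoir,
                       space = sys$space, times = t))
    if (length(v)) stop("invalid reservoir(s): ", paste(v, collapse = "; "))
  }
  n <- sys$space$n
  K <- matrix(0, n, n)
  for (vn in names(sys$reservoirs)) {
    emb <- sys$embeddings[[vn]]
    M <- reservoir_rates(sys$reservoirs[[vn]], t)
    vals <- M[, emb$lidx, drop = FALSE]         # psub$n x n
    Kv <- matrix(0, n, n)
    Kv[cbind(as.vector(emb$G),
             rep(seq_len(n), each = nrow(emb$G)))] <- as.vector(vals)
    K <- K + Kv
  }
  K
}

#' Marginal rate matrix of a coordinate set, if it exists
#'
#' For a unit `omega` the column sums of the global rate matrix grouped
#' over the destinations outside `omega` must not depend on the source
#' coordinates outside `omega`; the common value is the unit's own
#' generator.  `try_marginal_rate()` reports either the generator or the
#' maximal discrepancy with witnessing states; `marginal_rate()` raises a
#' condition of class `unitssl_independence_error` on failure.
#'
#' @param sys a `composite_system`, or a global rate matrix (then `space`
#'   must be given).
#' @param omega non-empty character vector of coordinate names.
#' @param t time at which to evaluate the global rates.
#' @param tol independence tolerance.
#' @param space required when `sys` is a bare matrix.
#' @export
try_marginal_rate <- function(sys, omega, t = 0, tol = 1e-10,
                              space = NULL) {
  if (inherits(sys, "composite_system")) {
    space <- sys$space
    K <- global_rate(sys, t)
  } else K <- sys
  omega <- check_coord_names(space, omega)
  if (!length(omega)) stop("omega must be non-empty")
  midx <- marginal_index(space, omega)
  sub <- subspace(space, omega)
  Mall <- rowsum(K, midx, reorder = TRUE)   # sub$n x n, grouped destinations
  Ko <- matrix(0, sub$n, sub$n)
  worst <- 0; witness <- NULL
  for (g in seq_len(sub$n)) {
    cols <- which(midx == g)
    ref <- Mall[, cols[1]]
    if (length(cols) > 1) {
      dev <- abs(Mall[, cols, drop = FALSE] - ref)
      d <- max(dev)
      if (d > worst) {
        worst <- d
        w <- which(dev == d, arr.ind = TRUE)[1, ]
        witness <- list(dest_marginal = w[1], source_a = cols[1],
                        source_b = cols[w[2]])
      }
    }
    Ko[, g] <- rowMeans(Mall[, cols, drop = FALSE])
  }
  if (worst <= tol)
    list(ok = TRUE, matrix = Ko, max_residual = worst, space = sub)
  else
    list(ok = FALSE, matrix = NULL, max_residual = worst,
         witness = witness, space = sub)
}

#' @rdname try_marginal_rate
#' @export
marginal_rate <- function(sys, omega, t = 0, tol = 1e-10, space = NULL) {
  res <- try_marginal_rate(sys, omega, t, tol, space)
  if (!res$ok) {
    cond <- structure(
      class = c("unitssl_independence_error", "error", "condition"),
      list(message = sprintf(
        "marginal dynamics of {%s} depends on outside coordinates (max residual %.3g)",
        paste(omega, collapse = ","), res$max_residual),
        call = sys.call(-1), witness = res$witness,
        max_residual = res$max_residual))
    stop(cond)
  }
  res$matrix
}

#' Default sample of protocol times for structural checks
#'
#' Segment endpoints plus `n_interior` interior points per segment; a
#' single time for constant protocols.
#'
#' @param sys a `composite_system`.
#' @param n_interior interior points per protocol segment.
#' @export
sample_times <- function(sys, n_interior = 10) {
  br <- sys$breaks
  if (!length(br)) {
    if (all(vapply(sys$reservoirs, `[[`, "", "kind") == "constant"))
      return(sys$t_range[1])
    br <- sys$t_range
  }
  br <- sort(unique(c(sys$t_range, br)))
  ts <- br
  for (i in seq_len(length(br) - 1)) {
    h <- br[i + 1] - br[i]
    ts <- c(ts, br[i] + h * seq_len(n_interior) / (n_interior + 1))
  }
  # stay clear of exact segment boundaries (segments are [t0, t1))
  eps <- 1e-9 * max(abs(br), 1)
  sort(unique(pmin(pmax(ts, br[1]), br[length(br)] - eps)))
}

#' Is a coordinate set a unit of the system?
#'
#' A unit is a coordinate set whose marginal dynamics is a self-contained
#' Markov chain: the marginal rate construction must succeed at every
#' sampled protocol time.
#'
#' @param sys a `composite_system`.
#' @param omega character vector of coordinate names.
#' @param times sample times (defaults to [sample_times()]).
#' @param tol independence tolerance.
#' @export
is_unit <- function(sys, omega, times = NULL, tol = 1e-10) {
  if (is.null(times)) times <- sample_times(sys)
  all(vapply(times, function(t) try_marginal_rate(sys, omega, t, tol)$ok,
             logical(1)))
}

#' Does the system only make single-coordinate transitions?
#'
#' `TRUE` iff at every sampled time every non-zero off-diagonal global
#' rate changes exactly one coordinate (the multipartite-process
#' property).
#'
#' @inheritParams is_unit
#' @export
is_multipartite <- function(sys, times = NULL) {
  if (is.null(times)) times <- sample_times(sys)
  st <- all_states(sys$space)
  for (t in times) {
    K <- global_rate(sys, t)
    nz <- which(abs(K) > 1e-14, arr.ind = TRUE)
    nz <- nz[nz[, 1] != nz[, 2], , drop = FALSE]
    if (!nrow(nz)) next
    nch <- rowSums(st[nz[, 1], , drop = FALSE] !=
                   st[nz[, 2], , drop = FALSE])
    if (any(nch > 1)) return(FALSE)
  }
  TRUE
}

#' Compatibility of nested rate matrices
#'
#' For `alpha` a subset of `omega`, the generator of `alpha` must equal
#' the generator of `omega` summed over the destinations of
#' `omega \ alpha`, independently of the source state of those
#' coordinates.
#'
#' @param K_alpha generator over the `alpha` sub-space.
#' @param K_omega generator over the `omega` sub-space.
#' @param omega_space the `joint_space` of `omega`.
#' @param alpha character vector of coordinate names, a subset of the
#'   names of `omega_space`.
#' @param tol tolerance.
#' @return list with `ok`, `max_residual` and (on failure) `witness`.
#' @export
check_rate_compatibility <- function(K_alpha, K_omega, omega_space, alpha,
                                     tol = 1e-10) {
  alpha <- check_coord_names(omega_space, alpha)
  asub <- subspace(omega_space, alpha)
  if (!all(dim(K_alpha) == asub$n) || !all(dim(K_omega) == omega_space$n))
    stop("generator dimensions do not match the supplied spaces")
  midx <- marginal_index(omega_space, alpha)
  Mall <- rowsum(K_omega, midx, reorder = TRUE)
  worst <- 0; witness <- NULL
  for (g in seq_len(asub$n)) {
    cols <- which(midx == g)
    dev <- abs(Mall[, cols, drop = FALSE] - K_alpha[, g])
    d <- max(dev)
    if (d > worst) {
      worst <- d
      w <- which(dev == d, arr.ind = TRUE)[1, ]
      witness <- list(dest_alpha = w[1], source_alpha = g,
                      source_full = cols[w[2]])
    }
  }
  list(ok = worst <= tol, max_residual = worst, witness = witness)
}
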