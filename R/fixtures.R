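# Packaged example systems and seeded random generators.
#
# Each builder returns a "fixture_bundle": the composite system, its unit
# structure, the initial distribution, the time window, and a map of
# expected values used by the test suite.

new_bundle <- function(sys, nstar, p0, ti, tf, expected) {
  structure(list(sys = sys, nstar = nstar, p0 = p0, ti = ti, tf = tf,
                 expected = expected),
            class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat("<fixture_bundle> ")
  print(x$sys)
  invisible(x)
}

#' Dense local rate matrix from an entry function
#'
#' Builds the (destination-puppet x source-leader) matrix of a reservoir:
#' `rate_fn(dest, src)` receives named 0-based tuples (dest over the
#' puppet coordinates, src over the leaders) and returns the off-diagonal
#' rate; diagonals are filled so columns sum to zero.
#'
#' @param space the `joint_space`.
#' @param puppets,leaders coordinate name sets.
#' @param rate_fn function of `(dest, src)` tuples.
#' @export
make_local_rates <- function(space, puppets, leaders, rate_fn) {
  psub <- subspace(space, puppets); lsub <- subspace(space, leaders)
  pst <- all_states(psub); lst <- all_states(lsub)
  M <- matrix(0, psub$n, lsub$n)
  for (cc in seq_len(lsub$n)) {
    src <- lst[cc, ]
    diag_row <- state_index(psub, src[psub$names])
    for (rr in seq_len(psub$n)) {
      if (rr == diag_row) next
      M[rr, cc] <- rate_fn(pst[rr, ], src)
    }
    M[diag_row, cc] <- -sum(M[, cc])
  }
  M
}

# Random strictly positive local matrix (weakly reversible by full
# support on single-reservoir transitions).
random_local_rates <- function(space, puppets, leaders, scale = 1) {
  make_local_rates(space, puppets, leaders,
                   function(dest, src) stats::runif(1, 0.2, 1.2) * scale)
}

#' Cell-sensing network of four subsystems
#'
#' Four binary subsystems in a multipartite process: the external medium
#' `x3` evolves autonomously; the receptor `x2` of the first cell reads
#' `x3`; the memory `x1` reads `x2`; the receptor `x4` of a second cell
#' also reads `x3`.  One reservoir per subsystem (singleton puppet sets);
#' leader sets `x3 -> {x3}`, `x2 -> {x2,x3}`, `x1 -> {x1,x2}`,
#' `x4 -> {x3,x4}`.  The packaged unit structure is
#' `{{x1,x2,x3}, {x3,x4}, {x3}}`: two roots, one leaf, height 2, and it
#' is tight.
#'
#' @param sizes cardinalities of the four subsystems (all >= 2).
#' @param seed RNG seed for the rate draws.
#' @param rate_scale overall rate scale.
#' @param t_final end of the default time window.
#' @return a `fixture_bundle`.
#' @export
build_fig1 <- function(sizes = c(2, 2, 2, 2), seed = 1, rate_scale = 1,
                       t_final = 2) {
  stopifnot(length(sizes) == 4, all(sizes >= 2))
  set.seed(seed)
  sp <- joint_space(stats::setNames(as.integer(sizes),
                                    c("x1", "x2", "x3", "x4")))
  rs <- list(
    reservoir("v1", "x1", c("x1", "x2"),
              random_local_rates(sp, "x1", c("x1", "x2"), rate_scale)),
    reservoir("v2", "x2", c("x2", "x3"),
              random_local_rates(sp, "x2", c("x2", "x3"), rate_scale)),
    reservoir("v3", "x3", "x3",
              random_local_rates(sp, "x3", "x3", rate_scale)),
    reservoir("v4", "x4", c("x3", "x4"),
              random_local_rates(sp, "x4", c("x3", "x4"), rate_scale)))
  sys <- composite_system(sp, rs, t_range = c(0, t_final))
  nstar <- unit_structure(list(c("x1", "x2", "x3"), c("x3", "x4"), "x3"),
                          coordinates = sp$names)
  p0 <- distribution(sp, as.numeric(stats::rgamma(sp$n, 1)),
                     normalize = TRUE)
  new_bundle(sys, nstar, p0, 0, t_final,
             expected = list(n_roots = 2, n_leaves = 1, height = 2,
                             multipartite = TRUE,
                             nu_x3 = "v3", non_unit = "x2"))
}

#' Three-subsystem conditional relaxation
#'
#' Three binary subsystems with unit structure
#' `A* = {{x1,x2}, {x2}, {x2,x3}}`: `x2` evolves autonomously while `x1`
#' and `x3` each read `x2`.  Initially `x1 = x3` with uniform probability
#' and `x2` is independent and uniform, so `S(p_ti) = 2 ln 2` and the
#' in-ex information is `ln 2`.  The protocol has two stages of length
#' `relax_time` each: first `x2` uniformizes (losing all memory of its
#' start) while `x1`, `x3` jiggle conditioned on `x2`; then `x2` freezes
#' and `x1`, `x3` relax onto seeded target conditionals `q(x1|x2)`,
#' `q(x3|x2)`, losing all memory of their starts.  The endpoint
#' conditional therefore factorizes as
#' `p(x1|x2) p(x3|x2) p(x2)`, which makes the final in-ex information
#' vanish; the factorization residual is verified (not assumed) and must
#' be below `1e-4`.
#'
#' @param seed RNG seed for rates and target conditionals.
#' @param relax_time duration of each stage.
#' @return a `fixture_bundle`; `expected$factorization_residual` holds
#'   the verified residual.
#' @export
build_example2 <- function(seed = 1, relax_time = 20) {
  set.seed(seed)
  sp <- joint_space(c(x1 = 2, x2 = 2, x3 = 2))
  Tt <- relax_time
  r2 <- stats::runif(1, 0.5, 1.5)
  # stage-1 conditional jiggle rates and stage-2 targets for x1 and x3
  jig <- function() matrix(stats::runif(4, 0.3, 1.3), 2, 2)  # [dir, x2]
  q_of <- function() stats::runif(2, 0.15, 0.85)  # q(1 | x2 = 0, 1)
  s_of <- function() stats::runif(1, 0.8, 1.6)
  mk_cond <- function(coord, up_down, q, s, stage) {
    # local matrix over puppet {coord}, leaders {coord, x2}
    make_local_rates(sp, coord, c(coord, "x2"), function(dest, src) {
      x2 <- src[["x2"]]
      if (stage == 1) {
        if (dest[[coord]] == 1) up_down[1, x2 + 1] else up_down[2, x2 + 1]
      } else {
        if (dest[[coord]] == 1) s * q[x2 + 1] else s * (1 - q[x2 + 1])
      }
    })
  }
  ud1 <- jig(); ud3 <- jig()
  q1 <- q_of(); q3 <- q_of()
  s1 <- s_of(); s3 <- s_of()
  seg <- function(m1, m2) list(list(t0 = 0, t1 = Tt, rates = m1),
                               list(t0 = Tt, t1 = 2 * Tt, rates = m2))
  flip2 <- matrix(c(-r2, r2, r2, -r2), 2, 2)
  zero2 <- matrix(0, 2, 2)
  rs <- list(
    reservoir("v1", "x1", c("x1", "x2"),
              seg(mk_cond("x1", ud1, q1, s1, 1),
                  mk_cond("x1", ud1, q1, s1, 2))),
    reservoir("v2", "x2", "x2", seg(flip2, zero2)),
    reservoir("v3", "x3", c("x2", "x3"),
              seg(mk_cond("x3", ud3, q3, s3, 1),
                  mk_cond("x3", ud3, q3, s3, 2))))
  sys <- composite_system(sp, rs)
  nstar <- unit_structure(list(c("x1", "x2"), "x2", c("x2", "x3")),
                          coordinates = sp$names)
  # initial: x1 = x3 uniformly, x2 independent uniform
  st <- all_states(sp)
  p0 <- distribution(sp, as.numeric(st[, "x1"] == st[, "x3"]) / 4)

  # verify the endpoint factorization instead of assuming it
  map <- conditional_map(sys, 0, 2 * Tt)
  pf_expect <- numeric(sp$n)
  for (k in seq_len(sp$n)) {
    x <- st[k, ]
    m1 <- if (x["x1"] == 1) q1[x["x2"] + 1] else 1 - q1[x["x2"] + 1]
    m3 <- if (x["x3"] == 1) q3[x["x2"] + 1] else 1 - q3[x["x2"] + 1]
    pf_expect[k] <- 0.5 * m1 * m3
  }
  resid <- max(abs(map$matrix - pf_expect))
  if (resid > 1e-4)
    stop("insufficient mixing: factorization residual ", format(resid),
         "; increase relax_time")
  new_bundle(sys, nstar, p0, 0, 2 * Tt,
             expected = list(S_initial = 2 * log(2), I_initial = log(2),
                             I_final = 0, B = log(2),
                             factorization_residual = resid))
}

#' Coarse-grained lattice walker with nutrient stores
#'
#' A walker on an `L*Ncg x L*Ncg` periodic lattice represented by
#' within-square coordinates `x1, x2` (cardinality `L`), the square index
#' `x3` (cardinality `Ncg^2`), and two nutrient stores `xA, xB`
#' (cardinalities `nA, nB`) whose dynamics read `(xA, x1)` and
#' `(xB, x2)` respectively.  The two walk reservoirs move `(x1, x3)` and
#' `(x2, x3)` jointly: interior steps change only `x1` (or `x2`), while a
#' step across a square boundary deterministically carries the matching
#' `x3` update - a simultaneous two-coordinate transition, so the process
#' is not multipartite.  All steps are symmetric at rate `rate`.
#'
#' The packaged height-2 unit structure is
#' `{{x1}, {x2}, {x1,x2,x3}, {x1,xA}, {x2,xB}}` (flush, but not tight:
#' the walk reservoirs' leader sets reach outside the leaf units).
#' For this structure the in-ex information reduces to
#' `I = S(A|1) + S(B|2) - S(A,B|1,2,3)`.  From a point-mass start, once
#' the lattice position has uniformized, the within-square coordinates
#' each gain `ln L` of entropy and the nutrient stores decouple given
#' the position (`S(A,B|1,2,3) = S(A|1) + S(B|2)` by translation
#' invariance), so the in-ex information returns to zero: the
#' strengthened bound is non-trivial only transiently for this
#' structure.
#'
#' @param L within-square cardinality.
#' @param Ncg number of coarse-grained squares per lattice side.
#' @param nA,nB nutrient-store cardinalities.
#' @param seed RNG seed for the nutrient rates.
#' @param rate hop rate of the symmetric walks.
#' @param t_final end time (long enough to uniformize the position).
#' @return a `fixture_bundle`.
#' @export
build_walker <- function(L = 2, Ncg = 4, nA = 2, nB = 2, seed = 1,
                         rate = 1, t_final = 30) {
  stopifnot(L >= 2, Ncg >= 2, nA >= 2, nB >= 2)
  set.seed(seed)
  sp <- joint_space(c(x1 = L, x2 = L, x3 = Ncg^2, xA = nA, xB = nB))
  if (sp$n > 20000) stop("walker joint space has ", sp$n,
                         " states; reduce L, Ncg or the store sizes")
  g12 <- function(g) c(g %/% Ncg, g %% Ncg)   # square index -> (row, col)
  walk_rates <- function(coord, axis) {
    # puppet/leader {coord, x3}; axis 1 uses the square row, axis 2 the col
    make_local_rates(sp, c(coord, "x3"), c(coord, "x3"),
                     function(dest, src) {
      a0 <- src[[coord]]; g0 <- g12(src[["x3"]])
      a1 <- dest[[coord]]; g1 <- g12(dest[["x3"]])
      other_same <- g0[3 - axis] == g1[3 - axis]
      if (!other_same) return(0)
      step_up <- if (a0 < L - 1) (a1 == a0 + 1 && g1[axis] == g0[axis])
                 else (a1 == 0 && g1[axis] == (g0[axis] + 1) %% Ncg)
      step_dn <- if (a0 > 0) (a1 == a0 - 1 && g1[axis] == g0[axis])
                 else (a1 == L - 1 && g1[axis] == (g0[axis] - 1 + Ncg) %% Ncg)
      if (isTRUE(step_up) || isTRUE(step_dn)) rate else 0
    })
  }
  store_rates <- function(store, pos) {
    up <- stats::runif(L, 0.4, 1.4); dn <- stats::runif(L, 0.4, 1.4)
    make_local_rates(sp, store, c(pos, store), function(dest, src) {
      d <- dest[[store]] - src[[store]]
      if (d == 1) up[src[[pos]] + 1]
      else if (d == -1) dn[src[[pos]] + 1]
      else 0
    })
  }
  rs <- list(
    reservoir("walk1", c("x1", "x3"), c("x1", "x3"), walk_rates("x1", 1)),
    reservoir("walk2", c("x2", "x3"), c("x2", "x3"), walk_rates("x2", 2)),
    reservoir("nutrA", "xA", c("x1", "xA"), store_rates("xA", "x1")),
    reservoir("nutrB", "xB", c("x2", "xB"), store_rates("xB", "x2")))
  sys <- composite_system(sp, rs, t_range = c(0, t_final))
  nstar <- unit_structure(
    list("x1", "x2", c("x1", "x2", "x3"), c("x1", "xA"), c("x2", "xB")),
    coordinates = sp$names)
  p0 <- delta_distribution(sp, rep(0L, 5))
  new_bundle(sys, nstar, p0, 0, t_final,
             expected = list(multipartite = FALSE, flush = TRUE,
                             tight = FALSE, height = 2, n_roots = 3,
                             n_leaves = 2,
                             position_entropy_gain = 2 * log(L),
                             final_cond_indep_residual = 1e-3))
}

#' Seeded random system conforming to a unit structure
#'
#' Constructs a multipartite system realizing any given unit structure:
#' each coordinate gets one reservoir with a singleton puppet set whose
#' leader set is the smallest unit containing the coordinate, and
#' strictly positive seeded off-diagonal rates.  The result passes
#' [validate_structure()] with every flag true (for structures without
#' vacuous units) and is bitwise-reproducible for a given seed.
#'
#' @param nstar a `unit_structure`.
#' @param space a `joint_space` whose names match the structure's
#'   coordinates.
#' @param seed RNG seed.
#' @param rate_scale overall rate scale.
#' @param t_range default time window attached to the system.
#' @export
random_unit_system <- function(nstar, space, seed = 1, rate_scale = 1,
                               t_range = c(0, 1)) {
  stopifnot(setequal(nstar$coordinates, space$names))
  set.seed(seed)
  rs <- lapply(space$names, function(i) {
    containing <- nstar$units[vapply(nstar$units, function(u) i %in% u,
                                     logical(1))]
    if (!length(containing))
      stop("coordinate ", i, " is in no unit")
    leaders <- Reduce(intersect, containing)
    reservoir(paste0("v_", i), i, leaders,
              random_local_rates(space, i, leaders, rate_scale))
  })
  composite_system(space, rs, t_range = t_range)
}

#' Seeded random unit structure of height at most 2
#'
#' Draws either a partition of the coordinates into disjoint units
#' (height 1) or a shared-core family: a small core unit plus arms
#' `core + A_j` over a partition `{A_j}` of the remaining coordinates
#' (height 2).
#'
#' @param coords character vector of coordinate names (>= 2).
#' @param seed RNG seed.
#' @export
random_height2_structure <- function(coords, seed = 1) {
  set.seed(seed)
  n <- length(coords)
  stopifnot(n >= 2)
  pick1 <- function(x) x[sample.int(length(x), 1)]   # safe for length 1
  part <- function(items, k) {
    grp <- c(seq_len(k), sample.int(k, length(items) - k, replace = TRUE))
    split(items, sample(grp))
  }
  if (n >= 3 && stats::runif(1) < 0.5) {
    core <- sample(coords, pick1(seq_len(min(2, n - 2))))
    rest <- setdiff(coords, core)
    k <- pick1(2:min(3, length(rest)))
    arms <- part(sample(rest), k)
    units <- c(list(core), lapply(arms, function(a) c(core, a)))
  } else {
    k <- pick1(2:n)
    units <- part(sample(coords), k)
  }
  unit_structure(units, coordinates = coords)
}
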