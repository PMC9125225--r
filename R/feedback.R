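# Feedback control: measurement channels, frozen-controller extended
# systems, lifted unit structures, and the information bounds on
# extractable work (kB T = 1, nats).

#' Measurement channel p(c | x)
#'
#' A noisy observation of the joint state with `n_c` controller outcomes.
#' The observation has no back-action: the system marginal after the
#' measurement equals the pre-measurement distribution by construction of
#' [joint_initial()].
#'
#' @param space the system `joint_space`.
#' @param n_c number of controller states.
#' @param probs `n_c x n_states(space)` matrix; column `x` is p(. | x)
#'   and must sum to 1 within `1e-9`.
#' @export
channel <- function(space, n_c, probs) {
  probs <- as.matrix(probs)
  if (!all(dim(probs) == c(n_c, space$n)))
    stop("probs must be n_c x n_states")
  if (any(probs < -1e-12)) stop("negative channel probabilities")
  probs[probs < 0] <- 0
  cs <- colSums(probs)
  if (any(abs(cs - 1) > 1e-9))
    stop("channel columns must sum to 1 (max deviation ",
         format(max(abs(cs - 1))), ")")
  structure(list(space = space, n_c = as.integer(n_c), probs = probs),
            class = "channel")
}

#' Extended space with a frozen controller coordinate
#'
#' The controller is prepended as the first (slowest-varying) coordinate,
#' so extended flat index `= c * n + i` for controller state `c` and
#' system flat index `i`.
#'
#' @param space system `joint_space`.
#' @param n_c controller cardinality.
#' @param cname controller coordinate name (must be fresh).
#' @export
extended_space <- function(space, n_c, cname = "C") {
  if (cname %in% space$names) stop("name '", cname, "' already in use")
  joint_space(stats::setNames(c(n_c, space$sizes),
                              c(cname, space$names)))
}

#' Joint distribution right after the measurement
#'
#' `p(c, x) = p(c|x) p_dagger(x)` on the extended space; the system
#' marginal equals `p_dagger` exactly.
#'
#' @param p_dagger pre-measurement system `distribution`.
#' @param ch a `channel` on the same space.
#' @param cname controller coordinate name.
#' @export
joint_initial <- function(p_dagger, ch, cname = "C") {
  stopifnot(identical(p_dagger$space$sizes, ch$space$sizes))
  esp <- extended_space(ch$space, ch$n_c, cname)
  blocks <- ch$probs * matrix(p_dagger$p, ch$n_c, ch$space$n, byrow = TRUE)
  distribution(esp, as.vector(t(blocks)))
}

#' Lift a unit structure to the controller-extended space
#'
#' Every unit `w` becomes `w + {C}`.  If two original units were
#' disjoint, their lifted intersection is the bare controller `{C}`,
#' which is then added as an extra unit to restore intersection closure;
#' because it sits at the bottom of every intersection chain, its
#' in-ex contributions cancel exactly and neither the in-ex information
#' nor the bound changes.  When every pair of original units overlaps,
#' the inclusion poset (hence the graph height) is unchanged; adding the
#' bare controller can raise the height by one.
#'
#' @param nstar a `unit_structure`.
#' @param cname controller coordinate name.
#' @export
lift_structure <- function(nstar, cname = "C") {
  lifted <- lapply(nstar$units, function(u) c(u, cname))
  if (length(closure_units(lifted)) != length(lifted))
    lifted <- c(lifted, list(cname))
  unit_structure(lifted, coordinates = c(nstar$coordinates, cname),
                 allow_full = nstar$allow_full)
}

#' Controller-extended composite system
#'
#' Adds a frozen controller coordinate: no reservoir moves it, but every
#' reservoir's leader set gains it, so the system rates may depend on the
#' measurement outcome.  `rates_by_c(vname, c)` returns the rate
#' specification of reservoir `vname` conditioned on controller state `c`
#' (0-based); `NULL` entries leave the reservoir c-independent.
#'
#' @param sys the system without the controller.
#' @param n_c controller cardinality.
#' @param rates_by_c `NULL` (fully c-independent) or a function
#'   `(vname, c) -> rates spec` (matrix or piecewise list).
#' @param cname controller coordinate name.
#' @export
extend_with_controller <- function(sys, n_c, rates_by_c = NULL,
                                   cname = "C") {
  esp <- extended_space(sys$space, n_c, cname)
  lift <- function(r) {
    specs <- lapply(seq_len(n_c) - 1L, function(c) {
      s <- if (is.null(rates_by_c)) NULL else rates_by_c(r$name, c)
      if (is.null(s)) r$rates else s
    })
    reservoir(r$name, r$puppets, c(cname, r$leaders),
              combine_c_specs(specs))
  }
  # the controller is frozen: its reservoir exists (puppet sets must
  # cover the coordinates) but never fires
  frozen <- reservoir("frozen_controller", cname, cname,
                      matrix(0, n_c, n_c))
  composite_system(esp, c(lapply(sys$reservoirs, lift), list(frozen)),
                   allow_duplicate_puppets = TRUE, t_range = sys$t_range)
}

# Combine per-controller-state rate specs into one spec over the
# extended leader space (controller-major column blocks).
combine_c_specs <- function(specs) {
  kinds <- vapply(specs, function(s) {
    if (is.matrix(s)) "constant" else if (is.function(s)) "callable"
    else "piecewise"
  }, "")
  if (all(kinds == "constant")) return(do.call(cbind, specs))
  if (any(kinds == "callable")) {
    evals <- lapply(specs, function(s) {
      if (is.matrix(s)) function(t) s
      else if (is.function(s)) s
      else function(t) piecewise_lookup(s, t)
    })
    return(function(t) do.call(cbind, lapply(evals, function(f) f(t))))
  }
  # piecewise (possibly mixed with constant): merge the breakpoints
  br <- sort(unique(unlist(lapply(specs, function(s) {
    if (is.matrix(s)) numeric(0)
    else c(vapply(s, `[[`, numeric(1), "t0"),
           vapply(s, `[[`, numeric(1), "t1"))
  }))))
  lapply(seq_len(length(br) - 1), function(k) {
    tm <- (br[k] + br[k + 1]) / 2
    M <- do.call(cbind, lapply(specs, function(s) {
      if (is.matrix(s)) s else piecewise_lookup(s, tm)
    }))
    list(t0 = br[k], t1 = br[k + 1], rates = M)
  })
}

piecewise_lookup <- function(segs, t) {
  t0 <- vapply(segs, `[[`, numeric(1), "t0")
  t1 <- vapply(segs, `[[`, numeric(1), "t1")
  k <- which(t >= t0 - 1e-12 & (t < t1 | seq_along(t1) == length(t1)))
  if (!length(k)) stop("time ", t, " outside piecewise protocol")
  segs[[max(k)]]$rates
}

inex_mi_with_controller <- function(dist, nstar, cname) {
  inclusion_exclusion_sum(function(u) {
    if (!length(u)) return(0)
    mutual_information(dist, u, cname)
  }, nstar)
}

#' Change of the strengthened bound due to feedback
#'
#' The difference between the bound on the controller-extended structure
#' and the bound on the original structure:
#' `B_M - B_N = Delta[inex-sum of I(X_w; C)] - Delta I(X_N; C)`,
#' where `Delta f = f(tf) - f(ti)`.  Both arguments live on the extended
#' space.
#'
#' @param p_ti,p_tf `distribution`s over the controller-extended space.
#' @param nstar the *original* `unit_structure` (without the controller).
#' @param cname controller coordinate name.
#' @export
feedback_bound_difference <- function(p_ti, p_tf, nstar, cname = "C") {
  stopifnot(cname %in% p_ti$space$names, cname %in% p_tf$space$names)
  allx <- nstar$coordinates
  (inex_mi_with_controller(p_tf, nstar, cname) -
     inex_mi_with_controller(p_ti, nstar, cname)) -
    (mutual_information(p_tf, allx, cname) -
       mutual_information(p_ti, allx, cname))
}

#' Work-extraction bounds under feedback control
#'
#' With a uniform Hamiltonian at both endpoints and all reservoirs at one
#' temperature (units with kB T = 1), the extractable work is bounded by
#' the structure-aware expression `Delta[inex-sum of S(X_w | C)]`; the
#' conventional bound ignoring the unit structure is `Delta S(X_N | C)`.
#' Both are returned, along with whether the structure-aware bound is the
#' smaller (recorded, not assumed).  The work interpretation additionally
#' assumes rate matrices tied to a Hamiltonian by local detailed balance;
#' the quantities themselves are purely information-theoretic.
#'
#' @inheritParams feedback_bound_difference
#' @return list with `structured`, `conventional`,
#'   `structured_le_conventional`.
#' @export
extractable_work_bound <- function(p_ti, p_tf, nstar, cname = "C") {
  condent <- function(dist, u) {
    if (!length(u)) return(0)
    conditional_entropy(dist, u, cname)
  }
  structured <-
    inclusion_exclusion_sum(function(u) condent(p_tf, u), nstar) -
    inclusion_exclusion_sum(function(u) condent(p_ti, u), nstar)
  conventional <- condent(p_tf, nstar$coordinates) -
    condent(p_ti, nstar$coordinates)
  list(structured = structured, conventional = conventional,
       structured_le_conventional = structured <= conventional + 1e-12)
}
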