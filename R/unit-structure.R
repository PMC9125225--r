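#' Unit structures
#'
#' A unit structure is a finite set of units (non-empty coordinate sets)
#' that covers all coordinates and is closed under non-empty pairwise
#' intersection.  By default the full coordinate set is excluded from the
#' structure (the in-ex machinery below assumes this); pass
#' `allow_full = TRUE` to permit it.
#'
#' @param units list of character vectors (one per unit).
#' @param coordinates full coordinate set; defaults to the union of the
#'   units.
#' @param allow_full permit the unit equal to all coordinates.
#' @param check if `TRUE` (default), require cover and intersection
#'   closure at construction.
#' @return an object of class `unit_structure` with units in canonical
#'   order (increasing size, then lexicographic).
#' @export
unit_structure <- function(units, coordinates = NULL, allow_full = FALSE,
                           check = TRUE) {
  units <- lapply(units, function(u) sort(unique(as.character(u))))
  if (!length(units) || any(lengths(units) == 0))
    stop("units must be a non-empty list of non-empty coordinate sets")
  keys <- vapply(units, paste, "", collapse = "|")
  units <- units[!duplicated(keys)]
  units <- units[order(lengths(units),
                       vapply(units, paste, "", collapse = "|"))]
  if (is.null(coordinates)) coordinates <- sort(unique(unlist(units)))
  coordinates <- as.character(coordinates)
  if (check) {
    if (!setequal(unlist(units), coordinates))
      stop("units must cover exactly the coordinate set")
    cl <- closure_units(units)
    if (length(cl) != length(units))
      stop("unit set is not closed under non-empty intersection; ",
           "use intersection_closure()")
    full <- vapply(units, function(u) setequal(u, coordinates), logical(1))
    if (any(full) && !allow_full)
      stop("the full coordinate set is excluded from unit structures by ",
           "default; pass allow_full = TRUE to include it")
  }
  structure(list(units = units, coordinates = coordinates,
                 allow_full = allow_full),
            class = "unit_structure")
}

#' @export
print.unit_structure <- function(x, ...) {
  cat("<unit_structure> ", length(x$units), " units over {",
      paste(x$coordinates, collapse = ","), "}:\n", sep = "")
  for (u in x$units) cat("  {", paste(u, collapse = ","), "}\n", sep = "")
  invisible(x)
}

unit_key <- function(u) paste(sort(u), collapse = "|")

# Smallest superset of a unit list closed under non-empty intersection.
closure_units <- function(units) {
  units <- lapply(units, function(u) sort(unique(as.character(u))))
  keys <- vapply(units, unit_key, "")
  units <- units[!duplicated(keys)]
  repeat {
    keys <- vapply(units, unit_key, "")
    added <- FALSE
    nu <- length(units)
    for (i in seq_len(nu)) for (j in seq_len(nu)) {
      if (j <= i) next
      w <- intersect(units[[i]], units[[j]])
      if (length(w) && !(unit_key(w) %in% keys)) {
        units <- c(units, list(sort(w)))
        keys <- c(keys, unit_key(w))
        added <- TRUE
      }
    }
    if (!added) break
  }
  units[order(lengths(units), vapply(units, paste, "", collapse = "|"))]
}

#' Close a unit list under non-empty intersections
#'
#' Returns the smallest superset of `units` closed under non-empty
#' pairwise intersection, as a `unit_structure`.  Idempotent.
#'
#' @param units list of character vectors.
#' @param coordinates,allow_full passed to [unit_structure()].
#' @export
intersection_closure <- function(units, coordinates = NULL,
                                 allow_full = FALSE) {
  if (!length(units)) stop("units must be non-empty")
  unit_structure(closure_units(units), coordinates = coordinates,
                 allow_full = allow_full)
}

#' Dependency graph of a unit structure
#'
#' Nodes are units; there is an edge from `w` to `w'` iff `w'` is a
#' strict subset of `w` with no intervening unit.  The graph is acyclic;
#' roots have no incoming edge, leaves no outgoing edge, and the height
#' of a node is the maximal number of nodes on a directed path starting
#' there (a leaf has height 1).
#'
#' @param nstar a `unit_structure`.
#' @return an object of class `dependency_graph` with fields `nodes`
#'   (unit list), `edges` (2-column index matrix), `parents`,
#'   `descendants`, `family`, `node_heights`.
#' @export
build_dependency_graph <- function(nstar) {
  units <- nstar$units
  nu <- length(units)
  is_subset <- function(a, b) all(a %in% b)
  sub <- matrix(FALSE, nu, nu)   # sub[i, j]: unit j strictly contains unit i
  for (i in seq_len(nu)) for (j in seq_len(nu))
    if (i != j && is_subset(units[[i]], units[[j]]) &&
        length(units[[i]]) < length(units[[j]])) sub[i, j] <- TRUE
  edges <- NULL
  for (j in seq_len(nu)) for (i in seq_len(nu)) {
    if (!sub[i, j]) next
    # intervening unit k with i < k < j?
    interv <- any(sub[i, ] & sub[, j])
    if (!interv) edges <- rbind(edges, c(from = j, to = i))
  }
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2,
                                      dimnames = list(NULL, c("from", "to")))
  children <- lapply(seq_len(nu), function(j) edges[edges[, 1] == j, 2])
  parents <- lapply(seq_len(nu), function(j) edges[edges[, 2] == j, 1])
  descendants <- lapply(seq_len(nu), function(j) which(sub[, j]))
  heights <- integer(nu)
  node_height <- function(j) {
    if (heights[j]) return(heights[j])
    ch <- children[[j]]
    h <- if (!length(ch)) 1L else 1L + max(vapply(ch, node_height, 0L))
    heights[j] <<- h
    h
  }
  for (j in seq_len(nu)) node_height(j)
  structure(
    list(nodes = units, edges = edges, children = children,
         parents = parents, descendants = descendants,
         family = lapply(seq_len(nu), function(j) union(j, descendants[[j]])),
         node_heights = heights),
    class = "dependency_graph")
}

#' @export
print.dependency_graph <- function(x, ...) {
  cat("<dependency_graph> ", length(x$nodes), " units, ",
      nrow(x$edges), " edges, height ", graph_height(x), "\n", sep = "")
  invisible(x)
}

#' Roots, leaves and height of a dependency graph
#' @param g a `dependency_graph` (or a `unit_structure`, converted on the
#'   fly).
#' @return `roots()`/`leaves()`: list of units; `graph_height()`: integer.
#' @export
roots <- function(g) {
  g <- as_graph(g)
  g$nodes[vapply(seq_along(g$nodes),
                 function(j) !length(g$parents[[j]]), logical(1))]
}

#' @rdname roots
#' @export
leaves <- function(g) {
  g <- as_graph(g)
  g$nodes[vapply(seq_along(g$nodes),
                 function(j) !length(g$children[[j]]), logical(1))]
}

#' @rdname roots
#' @export
graph_height <- function(g) {
  g <- as_graph(g)
  max(g$node_heights)
}

as_graph <- function(g) {
  if (inherits(g, "unit_structure")) build_dependency_graph(g) else g
}

#' Export a dependency graph in DOT (Graphviz) format
#' @param g a `dependency_graph` or `unit_structure`.
#' @param path file path.
#' @export
write_graph_dot <- function(g, path) {
  g <- as_graph(g)
  lab <- vapply(g$nodes, function(u)
    paste0("\"{", paste(u, collapse = ","), "}\""), "")
  lines <- c("digraph units {", paste0("  ", lab, ";"))
  if (nrow(g$edges))
    lines <- c(lines, paste0("  ", lab[g$edges[, 1]], " -> ",
                             lab[g$edges[, 2]], ";"))
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Inclusion-exclusion sum over a unit structure
#'
#' For a unit structure with units `w_1, ..., w_n`, computes
#' `sum_j f(w_j) - sum_{j<j'} f(w_j ∩ w_j') + ...` over all `2^n - 1`
#' non-empty index subsets, evaluating `f` on the intersection of each
#' subset.  Empty intersections contribute `f(empty) := 0`.  Duplicate
#' intersections are counted once per index subset (standard
#' inclusion-exclusion), and the result does not depend on the order of
#' the units.
#'
#' @param f function mapping a character vector of coordinate names to a
#'   number, or a named numeric vector keyed by `paste(sort(unit),
#'   collapse = "|")`.
#' @param nstar a `unit_structure` with at most 20 units.
#' @export
inclusion_exclusion_sum <- function(f, nstar) {
  units <- nstar$units
  n <- length(units)
  if (n > 20)
    stop("refusing inclusion-exclusion over ", n,
         " units (2^n subsets); coarsen the structure")
  fv <- if (is.function(f)) f else function(u) {
    k <- unit_key(u)
    if (!k %in% names(f)) stop("f has no value for unit {", k, "}")
    unname(f[[k]])
  }
  cache <- new.env(parent = emptyenv())
  eval_unit <- function(u) {
    if (!length(u)) return(0)
    k <- unit_key(u)
    if (!is.null(cache[[k]])) return(cache[[k]])
    val <- fv(u)
    assign(k, val, envir = cache)
    val
  }
  total <- 0
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) != 0)
    inter <- Reduce(intersect, units[idx])
    total <- total + (-1)^(length(idx) + 1) * eval_unit(inter)
  }
  total
}

#' In-ex information of a distribution under a unit structure
#'
#' The inclusion-exclusion sum of the marginal entropies of the units
#' minus the entropy of the joint distribution, in nats.  For pairwise
#' disjoint units this is the multi-information of the unit marginals
#' (the mutual information, for two units); for overlapping units it can
#' be negative.
#'
#' @param dist a `distribution` over the structure's coordinates.
#' @param nstar a `unit_structure`.
#' @export
in_ex_information <- function(dist, nstar) {
  stopifnot(all(nstar$coordinates %in% dist$space$names))
  if (!setequal(nstar$coordinates, dist$space$names))
    dist <- marginalize(dist, nstar$coordinates)
  inclusion_exclusion_sum(function(u) marginal_entropy(dist, u), nstar) -
    shannon_entropy(dist)
}

#' Validate a unit structure against a composite system
#'
#' Checks, with witnesses for every failure:
#' * `covers`: the units cover all coordinates;
#' * `intersection_closed`: closure under non-empty intersection;
#' * `units_are_units`: every member passes [is_unit()];
#' * `flush`: every simultaneous-transition coordinate set of the global
#'   rate matrix is contained in some unit;
#' * `no_vacuous`: no unit has all its coordinates covered by proper
#'   subunits;
#' * `no_equivalent`: no nested pair of units is indistinguishable (for
#'   every nested pair there are transitions changing a coordinate of the
#'   difference), checked structurally assuming full support;
#' * `tight`: for every unit, every reservoir affecting it has its whole
#'   leader set inside the unit.
#'
#' @param sys a `composite_system`.
#' @param nstar a `unit_structure`.
#' @param times protocol times to sample (defaults to [sample_times()]).
#' @return an object of class `structure_report`: named logical `flags`,
#'   list `witnesses`, and `all_ok`.
#' @export
validate_structure <- function(sys, nstar, times = NULL) {
  if (is.null(times)) times <- sample_times(sys)
  space <- sys$space
  flags <- c(covers = NA, intersection_closed = NA, units_are_units = NA,
             flush = NA, no_vacuous = NA, no_equivalent = NA, tight = NA)
  wit <- list()
  units <- nstar$units
  flags["covers"] <- setequal(unlist(units), space$names) &&
    all(unlist(units) %in% space$names)
  flags["intersection_closed"] <-
    length(closure_units(units)) == length(units)

  ok_units <- vapply(units, function(u) is_unit(sys, u, times), logical(1))
  flags["units_are_units"] <- all(ok_units)
  if (!all(ok_units))
    wit$non_units <- units[!ok_units]

  # flush: every simultaneous-change set is inside some unit
  flush_ok <- TRUE
  st <- all_states(space)
  for (t in times) {
    K <- global_rate(sys, t)
    nz <- which(abs(K) > 1e-14, arr.ind = TRUE)
    nz <- nz[nz[, 1] != nz[, 2], , drop = FALSE]
    for (k in seq_len(nrow(nz))) {
      chg <- space$names[st[nz[k, 1], ] != st[nz[k, 2], ]]
      if (!any(vapply(units, function(u) all(chg %in% u), logical(1)))) {
        flush_ok <- FALSE
        wit$flush <- list(t = t, changed = chg,
                          from = nz[k, 2], to = nz[k, 1])
        break
      }
    }
    if (!flush_ok) break
  }
  flags["flush"] <- flush_ok

  # vacuous units
  vac <- vapply(seq_along(units), function(i) {
    subs <- units[vapply(units, function(u)
      all(u %in% units[[i]]) && length(u) < length(units[[i]]), logical(1))]
    length(subs) > 0 && all(units[[i]] %in% unlist(subs))
  }, logical(1))
  flags["no_vacuous"] <- !any(vac)
  if (any(vac)) wit$vacuous <- units[vac]

  # equivalent nested pairs (structural check, full support assumed)
  equiv_ok <- TRUE
  for (i in seq_along(units)) for (j in seq_along(units)) {
    if (i == j) next
    wsmall <- units[[i]]; wbig <- units[[j]]
    if (!(all(wsmall %in% wbig) && length(wsmall) < length(wbig))) next
    if (!ok_units[j]) next
    diffc <- setdiff(wbig, wsmall)
    for (t in times) {
      res <- try_marginal_rate(sys, wbig, t)
      if (!res$ok) next
      stw <- all_states(res$space)
      nz <- which(abs(res$matrix) > 1e-12, arr.ind = TRUE)
      nz <- nz[nz[, 1] != nz[, 2], , drop = FALSE]
      moved <- FALSE
      for (k in seq_len(nrow(nz)))
        if (any(stw[nz[k, 1], diffc] != stw[nz[k, 2], diffc])) {
          moved <- TRUE; break
        }
      if (!moved) {
        equiv_ok <- FALSE
        wit$equivalent <- list(inner = wsmall, outer = wbig, t = t)
      }
    }
  }
  flags["no_equivalent"] <- equiv_ok

  # tightness
  tight_ok <- TRUE
  for (u in units) {
    for (v in reservoirs_affecting(sys, u)) {
      Lv <- sys$reservoirs[[v]]$leaders
      if (!all(Lv %in% u)) {
        tight_ok <- FALSE
        wit$tight <- list(unit = u, reservoir = v, leaders = Lv)
      }
    }
  }
  flags["tight"] <- tight_ok

  structure(list(flags = flags, witnesses = wit, all_ok = all(flags)),
            class = "structure_report")
}

#' @export
print.structure_report <- function(x, ...) {
  cat("<structure_report>\n")
  for (nm in names(x$flags))
    cat(sprintf("  %-20s %s\n", nm, x$flags[nm]))
  invisible(x)
}

#' Enumerate valid unit structures of dependency height at most 2
#'
#' Exhaustively searches families of units (coordinate subsets passing
#' [is_unit()]) for structures that pass [validate_structure()] with all
#' flags true and whose dependency graph has height at most 2.  Results
#' are sorted canonically (fewer units first, then lexicographically).
#' The joint space must have at most 12 coordinates; the search is
#' bounded by `budget` candidate families, and a partial result carries
#' attribute `exhausted = TRUE`.
#'
#' @param sys a `composite_system`.
#' @param max_units maximal number of units per structure.
#' @param allow_full include the trivial structure containing all
#'   coordinates as one unit.
#' @param budget maximal number of families examined.
#' @return list of `unit_structure` objects.
#' @export
enumerate_height2_structures <- function(sys, max_units = 6,
                                         allow_full = FALSE,
                                         budget = 200000) {
  nm <- sys$space$names
  if (length(nm) > 12)
    stop("subset search limited to 12 coordinates")
  times <- sample_times(sys)
  # candidate units: all proper non-empty subsets passing is_unit
  cands <- list()
  for (mask in seq_len(2^length(nm) - 1)) {
    u <- nm[bitwAnd(mask, 2^(seq_along(nm) - 1)) != 0]
    if (length(u) == length(nm)) next
    if (is_unit(sys, u, times)) cands <- c(cands, list(u))
  }
  out <- list()
  if (allow_full)
    out <- c(out, list(unit_structure(list(nm), allow_full = TRUE)))
  nc <- length(cands)
  exhausted <- FALSE
  tried <- 0
  if (nc) {
    for (mask in seq_len(2^nc - 1)) {
      idx <- which(bitwAnd(mask, 2^(seq_len(nc) - 1)) != 0)
      if (length(idx) > max_units) next
      tried <- tried + 1
      if (tried > budget) { exhausted <- TRUE; break }
      fam <- cands[idx]
      if (!setequal(unlist(fam), nm)) next
      if (length(closure_units(fam)) != length(fam)) next
      ns <- unit_structure(fam, coordinates = nm, check = FALSE)
      if (graph_height(ns) > 2) next
      rep <- validate_structure(sys, ns, times)
      if (rep$all_ok) out <- c(out, list(ns))
    }
  }
  keyfun <- function(s) paste(vapply(s$units, unit_key, ""), collapse = ";")
  out <- out[order(lengths(lapply(out, `[[`, "units")),
                   vapply(out, keyfun, ""))]
  attr(out, "exhausted") <- exhausted
  out
}
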