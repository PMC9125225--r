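#' Construct a joint state space from named coordinates
#'
#' A joint space is an ordered product of finite coordinates.  Each
#' coordinate has a unique name and a cardinality of at least 2; its states
#' are the integers `0, ..., cardinality - 1`.  Joint states are tuples with
#' one entry per coordinate, in the order the coordinates were declared.
#'
#' Flat enumeration is lexicographic with the *last* declared coordinate
#' varying fastest, and is stable across runs: the joint state
#' `(x_1, ..., x_N)` has flat index `1 + sum_i x_i * stride_i` with
#' `stride_N = 1` and `stride_i = prod(sizes[(i+1):N])`.  All vectors and
#' matrices in the package use this enumeration.
#'
#' @param sizes named integer vector of coordinate cardinalities (all >= 2),
#'   or an unnamed vector together with `names`.
#' @param names optional character vector of coordinate names.
#' @return an object of class `joint_space`.
#' @examples
#' sp <- joint_space(c(x1 = 2, x2 = 3))
#' n_states(sp)  # 6
#' @export
joint_space <- function(sizes, names = NULL) {
  if (!is.null(names)) {
    stopifnot(length(names) == length(sizes))
    names(sizes) <- names
  }
  nm <- base::names(sizes)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("coordinates must have unique, non-empty names")
  sizes <- as.integer(sizes)
  if (any(sizes < 2L)) stop("every coordinate cardinality must be >= 2")
  strides <- rev(cumprod(rev(c(sizes[-1L], 1L))))
  structure(
    list(names = nm, sizes = stats::setNames(sizes, nm),
         strides = stats::setNames(strides, nm),
         n = prod(sizes)),
    class = "joint_space")
}

#' @export
print.joint_space <- function(x, ...) {
  cat("<joint_space> ", x$n, " states: ",
      paste0(x$names, "(", x$sizes, ")", collapse = " x "), "\n", sep = "")
  invisible(x)
}

#' Number of joint states of a space
#' @param space a `joint_space`.
#' @return integer count of joint states.
#' @export
n_states <- function(space) space$n

check_coord_names <- function(space, A) {
  A <- as.character(A)
  bad <- setdiff(A, space$names)
  if (length(bad))
    stop("unknown coordinate name(s): ", paste(bad, collapse = ", "))
  A
}

#' Map joint-state tuples to flat indices and back
#'
#' @param space a `joint_space`.
#' @param states integer matrix (one row per joint state, columns in
#'   coordinate order, values 0-based) or a single state vector.
#' @return `state_index`: integer vector of 1-based flat indices.
#' @export
state_index <- function(space, states) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1L)
  if (ncol(states) != length(space$names))
    stop("state tuples must have one column per coordinate")
  if (any(states < 0L) || any(t(states) >= space$sizes))
    stop("state values out of range")
  as.integer(1L + states %*% space$strides)
}

#' @rdname state_index
#' @param idx integer vector of 1-based flat indices.
#' @return `index_state`: integer matrix of 0-based joint-state tuples.
#' @export
index_state <- function(space, idx) {
  idx <- as.integer(idx)
  if (any(idx < 1L) || any(idx > space$n)) stop("flat index out of range")
  rem <- idx - 1L
  out <- matrix(0L, nrow = length(idx), ncol = length(space$names),
                dimnames = list(NULL, space$names))
  for (i in seq_along(space$names)) {
    out[, i] <- rem %/% space$strides[i]
    rem <- rem %% space$strides[i]
  }
  out
}

#' Enumerate all joint states of a space
#' @param space a `joint_space`.
#' @return integer matrix with `n_states(space)` rows in flat-index order.
#' @export
all_states <- function(space) index_state(space, seq_len(space$n))

#' Human-readable labels ("x1=0,x2=1" -> "0,1") for every joint state
#' @param space a `joint_space`.
#' @export
state_labels <- function(space) {
  apply(all_states(space), 1L, paste, collapse = ",")
}

#' Sub-space spanned by a subset of coordinates
#'
#' Coordinate order of the parent space is preserved (so the sub-space
#' enumeration is independent of the order in which names are requested).
#'
#' @param space a `joint_space`.
#' @param A character vector of coordinate names.
#' @export
subspace <- function(space, A) {
  A <- check_coord_names(space, A)
  keep <- space$names[space$names %in% A]
  joint_space(space$sizes[keep])
}

# For each full flat index, the flat index of its A-marginal state.
marginal_index <- function(space, A) {
  sub <- subspace(space, A)
  st <- all_states(space)[, sub$names, drop = FALSE]
  state_index(sub, st)
}

#' Probability distribution over a joint space
#'
#' @param space a `joint_space`.
#' @param p numeric vector over flat indices; entries must be non-negative
#'   and sum to 1 within `1e-9`.
#' @param normalize if `TRUE`, rescale `p` to sum to 1 (never done
#'   silently).
#' @return an object of class `distribution`.
#' @export
distribution <- function(space, p, normalize = FALSE) {
  p <- as.numeric(p)
  if (length(p) != space$n) stop("probability vector has wrong length")
  if (any(p < -1e-12)) stop("negative probabilities")
  p[p < 0] <- 0
  s <- sum(p)
  if (normalize) {
    if (s <= 0) stop("cannot normalize an all-zero vector")
    p <- p / s
  } else if (abs(s - 1) > 1e-9) {
    stop("probabilities sum to ", format(s, digits = 12),
         "; pass normalize = TRUE to rescale")
  }
  structure(list(space = space, p = p), class = "distribution")
}

#' @export
print.distribution <- function(x, ...) {
  cat("<distribution> over", x$space$n, "states of",
      paste(x$space$names, collapse = ","), "\n")
  invisible(x)
}

#' Uniform and point-mass distributions
#' @param space a `joint_space`.
#' @export
uniform_distribution <- function(space) {
  distribution(space, rep(1 / space$n, space$n))
}

#' @rdname uniform_distribution
#' @param state 0-based joint-state tuple carrying all the mass.
#' @export
delta_distribution <- function(space, state) {
  p <- numeric(space$n)
  p[state_index(space, state)] <- 1
  distribution(space, p)
}

#' Marginal distribution over a coordinate subset
#'
#' Sums the joint distribution over the states of all coordinates outside
#' `A`; the result lives on `subspace(space, A)`.
#'
#' @param dist a `distribution`.
#' @param A non-empty character vector of coordinate names.
#' @export
marginalize <- function(dist, A) {
  A <- check_coord_names(dist$space, A)
  if (!length(A)) stop("A must be non-empty")
  sub <- subspace(dist$space, A)
  if (setequal(A, dist$space$names)) return(dist)
  idx <- marginal_index(dist$space, A)
  q <- as.numeric(rowsum(dist$p, idx, reorder = TRUE))
  distribution(sub, q, normalize = FALSE)
}

entropy_vec <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Shannon entropy in nats
#'
#' Natural logarithms throughout; terms with zero probability contribute
#' zero (`0 * log 0 := 0`).
#'
#' @param dist a `distribution`, or a bare probability vector.
#' @return entropy in nats, between 0 and `log(n_states)`.
#' @export
shannon_entropy <- function(dist) {
  if (inherits(dist, "distribution")) entropy_vec(dist$p) else entropy_vec(dist)
}

#' Marginal entropy of a coordinate subset, in nats
#' @param dist a `distribution`.
#' @param A character vector of coordinate names; `character(0)` gives 0.
#' @export
marginal_entropy <- function(dist, A) {
  if (!length(A)) return(0)
  shannon_entropy(marginalize(dist, A))
}

#' Mutual information between two disjoint coordinate sets, in nats
#'
#' `I(A;B) = S(A) + S(B) - S(A,B)`, always non-negative.
#'
#' @param dist a `distribution`.
#' @param A,B disjoint, non-empty character vectors of coordinate names.
#' @export
mutual_information <- function(dist, A, B) {
  A <- check_coord_names(dist$space, A); B <- check_coord_names(dist$space, B)
  if (length(intersect(A, B))) stop("A and B must be disjoint")
  if (!length(A) || !length(B)) stop("A and B must be non-empty")
  marginal_entropy(dist, A) + marginal_entropy(dist, B) -
    marginal_entropy(dist, union(A, B))
}

#' Conditional entropy S(A | B), in nats
#'
#' `S(A|B) = S(A,B) - S(B)`, non-negative.
#'
#' @inheritParams mutual_information
#' @export
conditional_entropy <- function(dist, A, B) {
  A <- check_coord_names(dist$space, A); B <- check_coord_names(dist$space, B)
  if (length(intersect(A, B))) stop("A and B must be disjoint")
  marginal_entropy(dist, union(A, B)) - marginal_entropy(dist, B)
}

#' Multi-information (total correlation) of a partition, in nats
#'
#' `sum_blocks S(block) - S(joint)`; with two blocks this is their mutual
#' information, and it vanishes iff the blocks are independent.
#'
#' @param dist a `distribution`.
#' @param blocks list of character vectors partitioning the coordinates.
#' @export
multi_information <- function(dist, blocks) {
  all_names <- unlist(blocks)
  if (anyDuplicated(all_names) || !setequal(all_names, dist$space$names))
    stop("blocks must partition the coordinate set")
  sum(vapply(blocks, function(b) marginal_entropy(dist, b), numeric(1))) -
    shannon_entropy(dist)
}

#' Column-stochastic conditional map over a joint space
#'
#' Column `j` is the distribution of the final state given initial flat
#' state `j`, i.e. the matrix of `p(x(tf) | x(ti))`.
#'
#' @param space a `joint_space`.
#' @param matrix square matrix with non-negative entries whose columns sum
#'   to 1 within `1e-9`.
#' @export
stochastic_map <- function(space, matrix) {
  if (!all(dim(matrix) == space$n)) stop("map has wrong dimensions")
  if (any(matrix < -1e-12)) stop("negative map entries")
  matrix[matrix < 0] <- 0
  cs <- colSums(matrix)
  if (any(abs(cs - 1) > 1e-9))
    stop("columns must sum to 1 (max deviation ",
         format(max(abs(cs - 1))), ")")
  structure(list(space = space, matrix = matrix), class = "stochastic_map")
}

#' Apply a conditional map to an initial distribution
#' @param map a `stochastic_map`.
#' @param dist a `distribution` on the same space.
#' @export
apply_map <- function(map, dist) {
  stopifnot(identical(map$space$sizes, dist$space$sizes))
  distribution(map$space, as.numeric(map$matrix %*% dist$p),
               normalize = TRUE)
}

#' Read and write distributions as CSV or JSON
#'
#' The CSV layout has one column per coordinate (0-based state values)
#' followed by a `probability` column; the JSON layout is an object mapping
#' comma-separated state tuples to probabilities.
#'
#' @param dist a `distribution`.
#' @param path file path.
#' @export
write_distribution_csv <- function(dist, path) {
  df <- as.data.frame(all_states(dist$space))
  df$probability <- dist$p
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distribution_csv
#' @param space the `joint_space` the file refers to.
#' @export
read_distribution_csv <- function(space, path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(space$names %in% names(df)) || !"probability" %in% names(df))
    stop("CSV must have one column per coordinate plus 'probability'")
  idx <- state_index(space, as.matrix(df[, space$names, drop = FALSE]))
  p <- numeric(space$n)
  p[idx] <- df$probability
  distribution(space, p)
}

#' @rdname write_distribution_csv
#' @export
write_distribution_json <- function(dist, path) {
  obj <- as.list(stats::setNames(dist$p, state_labels(dist$space)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_distribution_csv
#' @export
read_distribution_json <- function(space, path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- numeric(space$n)
  labs <- state_labels(space)
  bad <- setdiff(names(obj), labs)
  if (length(bad)) stop("unknown state labels: ", paste(bad, collapse = "; "))
  p[match(names(obj), labs)] <- as.numeric(obj)
  distribution(space, p)
}
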