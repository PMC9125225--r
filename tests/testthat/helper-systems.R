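# Shared builders for small test systems; all randomness is seeded by
# the caller.

# single bit flipping up at rate `up` and down at rate `down`
flip_system <- function(up = 1, down = 1, name = "x1", t_range = c(0, 1)) {
  sp <- joint_space(stats::setNames(2L, name))
  M <- matrix(c(-up, up, down, -down), 2, 2)
  composite_system(sp, list(reservoir("v", name, name, M)),
                   t_range = t_range)
}

# two independent bit-flip reservoirs at symmetric rates r1, r2
two_bit_system <- function(r1 = 1, r2 = 2) {
  sp <- joint_space(c(x1 = 2, x2 = 2))
  sym <- function(r) matrix(c(-r, r, r, -r), 2, 2)
  composite_system(sp, list(reservoir("v1", "x1", "x1", sym(r1)),
                            reservoir("v2", "x2", "x2", sym(r2))))
}

# seeded full-support random distribution
rdist <- function(space, seed) {
  set.seed(seed)
  distribution(space, as.numeric(stats::rgamma(space$n, 0.8)) + 1e-9,
               normalize = TRUE)
}

# seeded random composite system with a random height-<=2 structure
random_case <- function(seed, n_coords = NULL, t_range = c(0, 2)) {
  set.seed(seed)
  nc <- if (is.null(n_coords)) sample(3:4, 1) else n_coords
  coords <- paste0("x", seq_len(nc))
  nstar <- random_height2_structure(coords, seed = seed + 17)
  sp <- joint_space(stats::setNames(sample(2:3, nc, replace = TRUE),
                                    coords))
  sys <- random_unit_system(nstar, sp, seed = seed + 1000,
                            t_range = t_range)
  list(sys = sys, nstar = nstar, space = sp,
       p0 = rdist(sp, seed + 2000))
}

# Brute-force embedded rate matrix of one reservoir: entry by entry from
# the definition (transitions preserve non-puppet coordinates; rates read
# the source through the leader coordinates only).
brute_force_embed <- function(sys, vname, t) {
  r <- sys$reservoirs[[vname]]
  sp <- sys$space
  M <- reservoir_rates(r, t)
  psub <- subspace(sp, r$puppets); lsub <- subspace(sp, r$leaders)
  st <- all_states(sp)
  notP <- setdiff(sp$names, r$puppets)
  E <- matrix(0, sp$n, sp$n)
  for (i in seq_len(sp$n)) for (j in seq_len(sp$n)) {
    if (length(notP) && any(st[i, notP] != st[j, notP])) next
    E[i, j] <- M[state_index(psub, st[i, psub$names]),
                 state_index(lsub, st[j, lsub$names])]
  }
  E
}

# independent brute-force Schnakenberg sums over all ordered state pairs
brute_force_ep <- function(sys, p, t) {
  total <- 0
  n <- sys$space$n
  for (v in names(sys$reservoirs)) {
    E <- brute_force_embed(sys, v, t)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || E[i, j] <= 0 || p[j] <= 0) next
      total <- total + E[i, j] * p[j] *
        log((E[i, j] * p[j]) / (E[j, i] * p[i]))
    }
  }
  total
}

brute_force_ef <- function(sys, p, t) {
  total <- 0
  n <- sys$space$n
  for (v in names(sys$reservoirs)) {
    E <- brute_force_embed(sys, v, t)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || E[i, j] <= 0 || p[j] <= 0) next
      total <- total + E[i, j] * p[j] * log(E[i, j] / E[j, i])
    }
  }
  total
}

# the correlated three-bit initial state of the conditional-relaxation
# example: x1 = x3 uniformly, x2 uniform and independent
correlated_three_bits <- function() {
  sp <- joint_space(c(x1 = 2, x2 = 2, x3 = 2))
  st <- all_states(sp)
  distribution(sp, as.numeric(st[, "x1"] == st[, "x3"]) / 4)
}

example2_structure <- function() {
  unit_structure(list(c("x1", "x2"), "x2", c("x2", "x3")),
                 coordinates = c("x1", "x2", "x3"))
}
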