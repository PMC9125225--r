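perfect_x2_channel <- function(sp) {
  st <- all_states(sp)
  channel(sp, 2, t(cbind(st[, "x2"] == 0, st[, "x2"] == 1)))
}

test_that("channels validate and the post-measurement joint has the right marginals", {
  sp <- joint_space(c(x1 = 2, x2 = 2))
  expect_error(channel(sp, 2, matrix(0.4, 2, 4)), "sum to 1")
  ch_blind <- channel(sp, 2, matrix(0.5, 2, 4))
  d <- rdist(sp, 1)
  j <- joint_initial(d, ch_blind)
  expect_equal(marginalize(j, sp$names)$p, d$p)         # no back-action
  expect_equal(mutual_information(j, sp$names, "C"), 0) # blind channel
  # perfect measurement of a fair bit carries ln 2
  spb <- joint_space(c(x = 2))
  chp <- channel(spb, 2, diag(2))
  jb <- joint_initial(uniform_distribution(spb), chp)
  expect_equal(jb$p, c(0.5, 0, 0, 0.5))
  expect_equal(mutual_information(jb, "x", "C"), log(2))
})

test_that("a symmetric noisy readout of a fair bit carries ln 2 minus the noise entropy", {
  spb <- joint_space(c(x = 2))
  for (eps in c(0.05, 0.2, 0.35)) {
    ch <- channel(spb, 2, matrix(c(1 - eps, eps, eps, 1 - eps), 2, 2))
    j <- joint_initial(uniform_distribution(spb), ch)
    h2 <- -eps * log(eps) - (1 - eps) * log(1 - eps)
    # brute-force mutual information on the four extended states
    p <- j$p
    pc <- c(p[1] + p[2], p[3] + p[4])
    px <- c(p[1] + p[3], p[2] + p[4])
    oracle <- sum(p[p > 0] * log(p[p > 0])) -
      sum(pc * log(pc)) - sum(px * log(px))
    expect_equal(mutual_information(j, "x", "C"), oracle,
                 tolerance = 1e-12)
    expect_equal(mutual_information(j, "x", "C"), log(2) - h2,
                 tolerance = 1e-12)
  }
})

test_that("lifting a structure preserves unit count, closure and height", {
  astar <- example2_structure()
  m <- lift_structure(astar)
  expect_length(m$units, length(astar$units))
  expect_true(all(vapply(m$units, function(u) "C" %in% u, logical(1))))
  expect_equal(graph_height(m), graph_height(astar))
  single <- unit_structure(list(c("x1", "x2")),
                           coordinates = c("x1", "x2"),
                           allow_full = TRUE)
  ms <- lift_structure(single)
  expect_identical(ms$units[[1]], c("C", "x1", "x2"))
  # overlapping units: poset isomorphic, height preserved; disjoint
  # pairs force the bare controller in, which can add one level but
  # never changes the in-ex information
  esp <- joint_space(c(C = 2, x1 = 2, x2 = 2, x3 = 2, x4 = 2))
  for (s in 1:10) {
    ns <- random_height2_structure(paste0("x", 1:4), seed = s)
    m <- lift_structure(ns)
    disjoint <- any(vapply(seq_along(ns$units), function(i)
      any(vapply(seq_along(ns$units), function(j)
        i < j && !length(intersect(ns$units[[i]], ns$units[[j]])),
        logical(1))), logical(1)))
    if (!disjoint) {
      expect_length(m$units, length(ns$units))
      expect_equal(graph_height(m), graph_height(ns))
    } else {
      expect_lte(graph_height(m), graph_height(ns) + 1)
      # the bare controller unit contributes nothing to the in-ex value
      bare <- unit_structure(lapply(ns$units, function(u) c(u, "C")),
                             coordinates = c(ns$coordinates, "C"),
                             check = FALSE)
      d <- rdist(esp, s + 600)
      expect_equal(in_ex_information(d, m), in_ex_information(d, bare),
                   tolerance = 1e-12)
    }
  }
})

test_that("the feedback bound difference vanishes without information", {
  b <- build_example2(seed = 8)
  sp <- b$sys$space
  ch_blind <- channel(sp, 2, matrix(0.5, 2, sp$n))
  p_i <- joint_initial(b$p0, ch_blind)
  esys <- extend_with_controller(b$sys, 2)
  rec <- evolve(esys, p_i, b$ti, b$tf, n_steps = 600)
  p_f <- final_distribution(rec)
  expect_equal(feedback_bound_difference(p_i, p_f, b$nstar), 0,
               tolerance = 1e-9)
  # single-unit structure: the in-ex sum collapses onto I(X_N; C)
  single <- unit_structure(list(sp$names), coordinates = sp$names,
                           allow_full = TRUE)
  expect_equal(feedback_bound_difference(p_i, p_f, single), 0,
               tolerance = 1e-12)
})

test_that("B_M equals B_N plus the lifted-structure difference, exactly", {
  b <- build_example2(seed = 9)
  sp <- b$sys$space
  ch <- perfect_x2_channel(sp)
  p_i <- joint_initial(b$p0, ch)
  # controller-dependent stage-2 relaxation for x1
  set.seed(99)
  qs <- list(runif(2, 0.1, 0.9), runif(2, 0.1, 0.9))
  rbc <- function(vname, c) {
    if (vname != "v1") return(NULL)
    q <- qs[[c + 1]]
    stage2 <- make_local_rates(sp, "x1", c("x1", "x2"),
      function(dest, src) if (dest[["x1"]] == 1) q[src[["x2"]] + 1]
                          else 1 - q[src[["x2"]] + 1])
    list(list(t0 = 0, t1 = b$tf / 2,
              rates = reservoir_rates(b$sys$reservoirs$v1, 0)),
         list(t0 = b$tf / 2, t1 = b$tf, rates = stage2))
  }
  esys <- extend_with_controller(b$sys, 2, rbc)
  rec <- evolve(esys, p_i, b$ti, b$tf, n_steps = 900)
  p_f <- final_distribution(rec)
  # the controller marginal never moves
  expect_lt(max(abs(marginalize(p_f, "C")$p -
                    marginalize(p_i, "C")$p)), 1e-10)
  BM <- as.numeric(ssl_bound(p_i, p_f, lift_structure(b$nstar)))
  BN <- as.numeric(ssl_bound(marginalize(p_i, sp$names),
                             marginalize(p_f, sp$names), b$nstar))
  dd <- feedback_bound_difference(p_i, p_f, b$nstar)
  expect_equal(BM, BN + dd, tolerance = 1e-10)
  # term-by-term oracle for the A* structure:
  # inex-sum of I(X_w;C) = I(x1,x2;C) + I(x2,x3;C) - I(x2;C)
  inex_mi <- function(p) {
    mutual_information(p, c("x1", "x2"), "C") +
      mutual_information(p, c("x2", "x3"), "C") -
      mutual_information(p, "x2", "C")
  }
  oracle <- (inex_mi(p_f) - inex_mi(p_i)) -
    (mutual_information(p_f, sp$names, "C") -
       mutual_information(p_i, sp$names, "C"))
  expect_equal(dd, oracle, tolerance = 1e-12)
})

test_that("work bounds: structure-aware vs conventional, with a brute-force oracle", {
  b <- build_example2(seed = 10)
  sp <- b$sys$space
  ch <- perfect_x2_channel(sp)
  p_i <- joint_initial(b$p0, ch)
  esys <- extend_with_controller(b$sys, 2)
  rec <- evolve(esys, p_i, b$ti, b$tf, n_steps = 600)
  p_f <- final_distribution(rec)
  wb <- extractable_work_bound(p_i, p_f, b$nstar)
  # hand expansion of the in-ex sum over A*
  hand <- function(p) {
    conditional_entropy(p, c("x1", "x2"), "C") +
      conditional_entropy(p, c("x2", "x3"), "C") -
      conditional_entropy(p, "x2", "C")
  }
  expect_equal(wb$structured, hand(p_f) - hand(p_i), tolerance = 1e-12)
  expect_equal(wb$conventional,
               conditional_entropy(p_f, sp$names, "C") -
                 conditional_entropy(p_i, sp$names, "C"),
               tolerance = 1e-12)
  # single-unit structure: both bounds coincide
  single <- unit_structure(list(sp$names), coordinates = sp$names,
                           allow_full = TRUE)
  wbs <- extractable_work_bound(p_i, p_f, single)
  expect_equal(wbs$structured, wbs$conventional, tolerance = 1e-12)
})
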