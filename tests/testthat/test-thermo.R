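test_that("EF rate: symmetric rates give zero, biased flip matches the closed form", {
  sym <- flip_system(up = 1.4, down = 1.4)
  d <- rdist(sym$space, 1)
  expect_equal(ef_rate(sym, d, 0), 0)

  up <- 1.2; down <- 0.5
  sys <- flip_system(up = up, down = down)
  for (s in 1:5) {
    d <- rdist(sys$space, s)
    closed <- (up * d$p[1] - down * d$p[2]) * log(up / down)
    expect_equal(ef_rate(sys, d, 0), closed, tolerance = 1e-12)
    expect_equal(brute_force_ef(sys, d$p, 0), closed, tolerance = 1e-12)
  }
  # stationary detailed-balanced state: EF and EP both vanish
  pst <- distribution(sys$space, c(down, up) / (up + down))
  expect_equal(ef_rate(sys, pst, 0), 0, tolerance = 1e-12)
  expect_equal(ep_rate(sys, pst, 0), 0, tolerance = 1e-12)
})

test_that("EP rate equals the brute-force Schnakenberg sum and is non-negative", {
  for (s in 1:8) {
    cs <- random_case(s + 10)
    d <- cs$p0
    ep <- ep_rate(cs$sys, d, 0.3)
    expect_equal(ep, brute_force_ep(cs$sys, d$p, 0.3), tolerance = 1e-12)
    expect_gte(ep, -1e-10)
    # EP = dS/dt + EF
    expect_equal(ep, entropy_rate(cs$sys, d, 0.3) +
                     ef_rate(cs$sys, d, 0.3), tolerance = 1e-8)
  }
})

test_that("EF is additive over disjoint units and obeys the signed-measure extension", {
  b <- build_fig1(seed = 21)
  d <- rdist(b$sys$space, 3)
  efA <- ef_rate(b$sys, d, 0, c("x1", "x2", "x3"))
  ef3 <- ef_rate(b$sys, d, 0, "x3")
  ef34 <- ef_rate(b$sys, d, 0, c("x3", "x4"))
  # nu is disjoint for {x1,x2,x3} vs... use the two root units' difference
  diff <- ef_rate(b$sys, d, 0, scope = list(c("x1", "x2", "x3"), "x3"))
  expect_equal(diff, efA - ef3, tolerance = 1e-12)
  # disjoint-unit additivity on a product system
  sys <- two_bit_system(1.1, 0.6)
  dd <- rdist(sys$space, 4)
  expect_equal(ef_rate(sys, dd, 0, "x1") + ef_rate(sys, dd, 0, "x2"),
               ef_rate(sys, dd, 0, c("x1", "x2"), check = FALSE),
               tolerance = 1e-10)
  expect_equal(ef_rate(sys, dd, 0, c("x1", "x2"), check = FALSE),
               ef_rate(sys, dd, 0, "global"), tolerance = 1e-12)
  expect_true(is.numeric(ef34))
})

test_that("irreversible transitions are rejected by name", {
  sp <- joint_space(c(x1 = 2))
  oneway <- matrix(c(-1, 1, 0, 0), 2, 2)
  sys <- composite_system(sp, list(reservoir("v", "x1", "x1", oneway)))
  d <- uniform_distribution(sp)
  expect_error(ef_rate(sys, d, 0), "irreversible")
  expect_error(ep_rate(sys, d, 0), "irreversible")
})

test_that("unit-scope EP requires tightness and a genuine unit", {
  b <- build_walker(L = 2, Ncg = 2, nA = 2, nB = 2, t_final = 10)
  d <- rdist(b$sys$space, 5)
  expect_error(ep_rate(b$sys, d, 0, "x1", check = FALSE), "not tight")
  b2 <- build_example2(seed = 5)
  d2 <- rdist(b2$sys$space, 6)
  expect_gte(ep_rate(b2$sys, d2, 1, c("x1", "x2"), check = FALSE), -1e-12)
  expect_error(ep_rate(b2$sys, d2, 1, "x1"), "not a unit")
})

test_that("a frozen system produces a zero report", {
  sp <- joint_space(c(x1 = 2, x2 = 2))
  zsys <- composite_system(sp, list(
    reservoir("v1", "x1", "x1", matrix(0, 2, 2)),
    reservoir("v2", "x2", "x2", matrix(0, 2, 2))))
  d <- rdist(sp, 7)
  rec <- evolve(zsys, d, 0, 1, n_steps = 16)
  ns <- unit_structure(list("x1", "x2"), coordinates = c("x1", "x2"))
  tr <- integrate_thermo(zsys, rec, ns)
  expect_equal(tr$sigma_N, 0)
  expect_equal(unname(tr$sigma), c(0, 0))
  expect_equal(tr$B, 0)
})

test_that("integrated reports satisfy the decomposition identities and inequalities", {
  b <- build_example2(seed = 6)
  rec <- evolve(b$sys, b$p0, b$ti, b$tf, n_steps = 1200)
  tr <- integrate_thermo(b$sys, rec, b$nstar, tol = 1e-4)
  expect_lt(tr$residuals$ef_pointwise, 1e-8)
  expect_lt(abs(tr$residuals$ep_integrated), 1e-5)
  expect_gte(tr$sigma_N, log(2) - 1e-3)
  expect_true(all(tr$checks))
  ci <- check_inequalities(tr)
  expect_true(ci$all_ok)
  expect_true(all(c("nested", "disjoint_sum", "substructure",
                    "second_law", "ssl") %in% ci$details$kind))
})

test_that("too coarse a grid raises a refinement hint instead of silent error", {
  b <- build_example2(seed = 7)
  rec <- evolve(b$sys, b$p0, b$ti, b$tf, n_steps = 16)
  expect_error(integrate_thermo(b$sys, rec, b$nstar, tol = 1e-10),
               "n_steps")
})

test_that("the strengthened bound depends only on the endpoint distributions", {
  astar <- example2_structure()
  d <- correlated_three_bits()
  expect_equal(as.numeric(ssl_bound(d, d, astar)), 0)
  expect_true(attr(ssl_bound(d, d, astar), "guaranteed"))
  # a height-3 chain is flagged as not guaranteed
  chain <- unit_structure(list("a", c("a", "b"), c("a", "b", "c")),
                          coordinates = c("a", "b", "c", "d"),
                          check = FALSE)
  expect_false(attr(ssl_bound(rdist(joint_space(c(a = 2, b = 2, c = 2,
                                                  d = 2)), 1),
                              rdist(joint_space(c(a = 2, b = 2, c = 2,
                                                  d = 2)), 2),
                              chain), "guaranteed"))
})

test_that("independent relaxations of correlated bits lose exactly their mutual information", {
  # two correlated bits, each relaxing independently to uniform
  sp <- joint_space(c(x1 = 2, x2 = 2))
  p_i <- distribution(sp, c(0.4, 0.1, 0.1, 0.4))
  sys <- two_bit_system(1, 1.3)
  rec <- evolve(sys, p_i, 0, 25, n_steps = 200)
  p_f <- final_distribution(rec)
  ns <- unit_structure(list("x1", "x2"), coordinates = c("x1", "x2"))
  mi_drop <- mutual_information(p_i, "x1", "x2") -
    mutual_information(p_f, "x1", "x2")
  expect_equal(example1_bound(p_i, p_f, ns), mi_drop, tolerance = 1e-9)
  expect_equal(example1_bound(p_i, p_f, ns),
               as.numeric(ssl_bound(p_i, p_f, ns)), tolerance = 1e-12)
  expect_gte(example1_bound(p_i, p_f, ns), 0)
  # a product start has nothing to lose
  prod0 <- uniform_distribution(sp)
  rec0 <- evolve(sys, prod0, 0, 5, n_steps = 50)
  expect_equal(example1_bound(prod0, final_distribution(rec0), ns), 0,
               tolerance = 1e-9)
})

test_that("reports serialize to JSON with the documented keys", {
  b <- build_fig1(seed = 22)
  rec <- evolve(b$sys, b$p0, 0, 1, n_steps = 300)
  tr <- integrate_thermo(b$sys, rec, b$nstar, tol = 1e-4)
  f <- tempfile(fileext = ".json")
  write_report_json(tr, f)
  obj <- jsonlite::read_json(f)
  expect_true(all(c("Q", "sigma", "I_initial", "I_final", "B",
                    "residuals", "checks") %in% names(obj)))
  expect_equal(obj$B, tr$B, tolerance = 1e-12)
})
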