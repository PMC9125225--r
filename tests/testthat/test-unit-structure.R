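test_that("intersection closure adds exactly the missing overlaps and is idempotent", {
  ns <- intersection_closure(list(c("a", "b"), c("b", "c")))
  expect_length(ns$units, 3)
  expect_true(any(vapply(ns$units, identical, TRUE, "b")))
  ns2 <- intersection_closure(ns$units)
  expect_identical(ns2$units, ns$units)
  # walker root units: closure adds the two within-square coordinates
  ns3 <- intersection_closure(list(c("xA", "x1"), c("xB", "x2"),
                                   c("x1", "x2", "x3")))
  expect_length(ns3$units, 5)
  keys <- vapply(ns3$units, paste, "", collapse = "|")
  expect_true(all(c("x1", "x2") %in% keys))
  expect_error(intersection_closure(list()), "non-empty")
})

test_that("constructor rejects unclosed families and the full set by default", {
  expect_error(unit_structure(list(c("a", "b"), c("b", "c")),
                              coordinates = c("a", "b", "c")),
               "not closed")
  expect_error(unit_structure(list(c("a", "b")),
                              coordinates = c("a", "b")),
               "allow_full")
  expect_silent(unit_structure(list(c("a", "b")),
                               coordinates = c("a", "b"),
                               allow_full = TRUE))
})

test_that("dependency graphs report roots, leaves and height", {
  ns <- unit_structure(list(c("x1", "x2", "x3"), c("x3", "x4"), "x3"),
                       coordinates = paste0("x", 1:4))
  g <- build_dependency_graph(ns)
  expect_length(roots(g), 2)
  expect_length(leaves(g), 1)
  expect_equal(graph_height(g), 2)
  expect_identical(leaves(g)[[1]], "x3")

  single <- unit_structure(list("a"), coordinates = "a",
                           allow_full = TRUE)
  expect_equal(graph_height(single), 1)

  walker <- unit_structure(
    list("x1", "x2", c("x1", "x2", "x3"), c("x1", "xA"), c("x2", "xB")),
    coordinates = c("x1", "x2", "x3", "xA", "xB"))
  expect_equal(graph_height(walker), 2)
  expect_length(roots(walker), 3)
  expect_length(leaves(walker), 2)
})

test_that("DOT export lists every unit and every edge", {
  ns <- unit_structure(list(c("x1", "x2", "x3"), c("x3", "x4"), "x3"),
                       coordinates = paste0("x", 1:4))
  f <- tempfile(fileext = ".dot")
  write_graph_dot(ns, f)
  txt <- readLines(f)
  expect_length(grep("->", txt), 2)
  expect_length(grep("\\{", grep("->", txt, invert = TRUE, value = TRUE)),
                3 + 1)   # three node lines plus the digraph line
})

test_that("inclusion-exclusion expands per index subset, order-independently", {
  vals <- c("a" = 5, "a|b" = 2, "b" = 3, "b|c" = 7, "c" = 11)
  f <- function(u) unname(vals[paste(sort(u), collapse = "|")])
  one <- unit_structure(list(c("a", "b")), coordinates = c("a", "b"),
                        allow_full = TRUE)
  expect_equal(inclusion_exclusion_sum(f, one), 2)
  two <- unit_structure(list("a", "c"), coordinates = c("a", "c"))
  expect_equal(inclusion_exclusion_sum(f, two), 5 + 11)
  # {a,b}, {b}, {b,c}: hand expansion over the 7 subsets gives
  # f(ab) + f(b) + f(bc) - 3 f(b) + f(b) = f(ab) + f(bc) - f(b)
  astar <- unit_structure(list(c("a", "b"), "b", c("b", "c")),
                          coordinates = c("a", "b", "c"))
  expect_equal(inclusion_exclusion_sum(f, astar), 2 + 7 - 3)
  # unit order is canonicalized, so permuted input gives the same value
  astar2 <- unit_structure(list(c("b", "c"), c("a", "b"), "b"),
                           coordinates = c("a", "b", "c"))
  expect_equal(inclusion_exclusion_sum(f, astar2),
               inclusion_exclusion_sum(f, astar))
  big <- unit_structure(lapply(1:21, function(i) paste0("z", i)),
                        coordinates = paste0("z", 1:21))
  expect_error(inclusion_exclusion_sum(function(u) 1, big), "refusing")
})

test_that("in-ex information generalizes mutual and multi-information", {
  sp <- joint_space(c(a = 2, b = 2, c = 2))
  singles <- unit_structure(list("a", "b", "c"),
                            coordinates = c("a", "b", "c"))
  expect_equal(in_ex_information(uniform_distribution(sp), singles), 0)
  pair <- unit_structure(list(c("a", "b"), "c"),
                         coordinates = c("a", "b", "c"))
  for (s in 1:30) {
    d <- rdist(sp, s + 300)
    expect_equal(in_ex_information(d, pair),
                 mutual_information(d, c("a", "b"), "c"),
                 tolerance = 1e-12)
    expect_equal(in_ex_information(d, singles),
                 multi_information(d, list("a", "b", "c")),
                 tolerance = 1e-12)
  }
})

test_that("the correlated three-bit state has in-ex information ln 2, its factorized endpoint 0", {
  astar <- example2_structure()
  expect_equal(in_ex_information(correlated_three_bits(), astar), log(2))
  # any distribution of the form p(x2) q(x1|x2) q'(x3|x2) has zero
  # in-ex information under this structure
  sp <- joint_space(c(x1 = 2, x2 = 2, x3 = 2))
  set.seed(42)
  for (rep in 1:5) {
    p2 <- runif(1, 0.2, 0.8); q1 <- runif(2); q3 <- runif(2)
    st <- all_states(sp)
    p <- vapply(seq_len(sp$n), function(k) {
      x <- st[k, ]
      px2 <- if (x["x2"] == 1) p2 else 1 - p2
      m1 <- if (x["x1"] == 1) q1[x["x2"] + 1] else 1 - q1[x["x2"] + 1]
      m3 <- if (x["x3"] == 1) q3[x["x2"] + 1] else 1 - q3[x["x2"] + 1]
      px2 * m1 * m3
    }, numeric(1))
    d <- distribution(sp, p, normalize = TRUE)
    expect_equal(in_ex_information(d, astar), 0, tolerance = 1e-12)
  }
})

test_that("structure validation flags cover, vacuity, tightness and unit-ness", {
  # a two-coordinate autonomous system: {{N}} passes everything
  sys <- two_bit_system()
  full <- unit_structure(list(c("x1", "x2")),
                         coordinates = c("x1", "x2"), allow_full = TRUE)
  rep_full <- validate_structure(sys, full)
  expect_true(rep_full$all_ok)

  # {x1},{x2},{x1,x2}: the big unit is vacuous
  vac <- unit_structure(list("x1", "x2", c("x1", "x2")),
                        coordinates = c("x1", "x2"), allow_full = TRUE)
  rep_vac <- validate_structure(sys, vac)
  expect_false(rep_vac$flags[["no_vacuous"]])
  expect_length(rep_vac$witnesses$vacuous, 1)

  b <- build_fig1(seed = 13)
  rep1 <- validate_structure(b$sys, b$nstar)
  expect_true(rep1$all_ok)

  # declaring {x2} a unit is caught
  badns <- unit_structure(list("x2", c("x1", "x2"), c("x2", "x3"),
                               c("x2", "x4")),
                          coordinates = paste0("x", 1:4))
  rep2 <- validate_structure(b$sys, badns)
  expect_false(rep2$flags[["units_are_units"]])
})

test_that("height-2 enumeration recovers the packaged structures", {
  sys <- two_bit_system()
  found <- enumerate_height2_structures(sys)
  keys <- vapply(found, function(s)
    paste(vapply(s$units, paste, "", collapse = ","), collapse = ";"), "")
  expect_true("x1;x2" %in% keys)

  b1 <- build_fig1(seed = 14)
  keys1 <- vapply(enumerate_height2_structures(b1$sys), function(s)
    paste(vapply(s$units, paste, "", collapse = ","), collapse = ";"), "")
  expect_true("x3;x3,x4;x1,x2,x3" %in% keys1)

  b2 <- build_example2(seed = 4)
  found2 <- enumerate_height2_structures(b2$sys)
  keys2 <- vapply(found2, function(s)
    paste(vapply(s$units, paste, "", collapse = ","), collapse = ";"), "")
  expect_true("x2;x1,x2;x2,x3" %in% keys2)
  # every member of every returned structure is a unit of the system
  for (s in found2) for (u in s$units)
    expect_true(is_unit(b2$sys, u))
})
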