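test_that("triangles are enumerated once in canonical order", {
  expect_equal(enumerate_triangles(lung_network()),
               list(c("ConCT", "RT", "SeqCT")))

  star <- nma_network(data.frame(study_id = paste0("s", 1:3),
                                 treat_ref = "A", treat_alt = c("B", "C", "D"),
                                 effect = 0, se = 0.1))
  expect_length(enumerate_triangles(star), 0)

  k4 <- consistent_network(t = 4, seed = 5)  # complete graph on 4 nodes
  expect_length(enumerate_triangles(k4), 4)
})

test_that("Bucher test composes indirect evidence through the third arm", {
  lung <- lung_network()
  bt <- bucher_test(lung, c("RT", "SeqCT", "ConCT"),
                    comparison = c("RT", "ConCT"))
  expect_equal(bt$indirect, -0.311, tolerance = 1e-12)
  expect_equal(bt$omega, 0.173, tolerance = 1e-12)
  # z computed at full precision; 0.173/0.082 with the rounded SE gives 2.11
  expect_lt(abs(bt$z - 2.11), 0.011)
  expect_lt(abs(bt$p - 0.035), 0.0015)

  db <- diabetes_loop_network()
  bt2 <- bucher_test(db, c("metf", "sulf", "rosi"),
                     comparison = c("sulf", "rosi"))
  expect_equal(bt2$omega, 0.757, tolerance = 1e-12)
  expect_lt(abs(bt2$z - 3.07), 0.01)
  expect_lt(abs(bt2$p - 0.002), 5e-4)

  # identical direct and indirect evidence: omega = 0, p = 1
  bt3 <- bucher_test(triangle_network(0.2, 0.5, 0.3), c("A", "B", "C"),
                     comparison = c("A", "C"))
  expect_equal(bt3$omega, 0)
  expect_equal(bt3$p, 1)

  # z^2 does not depend on which edge is tested
  net <- triangle_network(0.1, 0.7, -0.2, 0.1, 0.2, 0.15)
  zs <- vapply(list(c("A", "B"), c("A", "C"), c("B", "C")), function(cmp) {
    bucher_test(net, c("A", "B", "C"), comparison = cmp)$z^2
  }, numeric(1))
  expect_equal(max(zs) - min(zs), 0, tolerance = 1e-8)
})

test_that("Bucher test refuses loops without two-arm direct evidence", {
  # B:C edge exists only inside the three-arm design
  net <- nma_network(data.frame(
    study_id = c("m", "m", "s2", "s3"),
    treat_ref = c("A", "A", "A", "A"),
    treat_alt = c("B", "C", "B", "C"),
    effect = c(0.1, 0.2, 0.1, 0.2), se = 0.1,
    shared_arm_variance = c(0.004, 0.004, NA, NA)))
  expect_error(bucher_test(net, c("A", "B", "C")), "two-arm direct evidence")
  expect_error(bucher_test(net, c("A", "B")), "three distinct")
})

test_that("node splitting agrees with Bucher in a single loop", {
  set.seed(83)
  for (i in 1:6) {
    v <- random_triangle_values()
    net <- triangle_network(v$theta[1], v$theta[2], v$theta[3],
                            sqrt(v$s2[1]), sqrt(v$s2[2]), sqrt(v$s2[3]))
    ns <- node_split(net, c("A", "C"))
    bt <- bucher_test(net, c("A", "B", "C"), comparison = c("A", "C"))
    expect_equal(ns$difference, bt$omega, tolerance = 1e-8)
    expect_equal(ns$se_difference, sqrt(bt$var_omega), tolerance = 1e-8)
    expect_equal(ns$difference, ns$direct - ns$indirect, tolerance = 1e-10)
    expect_equal(ns$se_difference^2, ns$se_direct^2 + ns$se_indirect^2,
                 tolerance = 1e-10)
  }
})

test_that("node split orientation flips signs but not the test", {
  net <- triangle_network(0.1, 0.7, -0.2, 0.1, 0.2, 0.15)
  a <- node_split(net, c("A", "C"))
  b <- node_split(net, c("C", "A"))
  expect_equal(a$direct, -b$direct, tolerance = 1e-12)
  expect_equal(a$indirect, -b$indirect, tolerance = 1e-12)
  expect_equal(a$difference, -b$difference, tolerance = 1e-12)
  expect_equal(abs(a$z), abs(b$z), tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("lung node splits all carry the same inconsistency magnitude", {
  res <- node_split_all(lung_network())
  expect_equal(nrow(res), 3L)
  expect_equal(abs(res$difference), rep(0.173, 3), tolerance = 1e-10)
  expect_equal(res$se_difference, rep(0.0816, 3), tolerance = 1e-3)
  row <- res[res$comparison == "SeqCT vs ConCT", ]
  expect_equal(row$direct, 0.179, tolerance = 1e-12)
  expect_equal(row$indirect, 0.006, tolerance = 1e-12)
})

test_that("unsplittable comparisons are refused", {
  # pendant edge C:D has no indirect path
  net <- nma_network(data.frame(study_id = paste0("s", 1:4),
                                treat_ref = c("A", "A", "B", "C"),
                                treat_alt = c("B", "C", "C", "D"),
                                effect = c(0.1, 0.2, 0.1, 0.4), se = 0.1))
  expect_error(node_split(net, c("C", "D")), "not splittable")
  # no direct evidence at all
  expect_error(node_split(net, c("B", "D")), "no direct evidence")
  # node_split_all skips them and keeps the splittable loop
  res <- suppressMessages(node_split_all(net))
  expect_setequal(res$comparison, c("B vs A", "C vs A", "C vs B"))

  star <- nma_network(data.frame(study_id = paste0("s", 1:3),
                                 treat_ref = "A", treat_alt = c("B", "C", "D"),
                                 effect = 0, se = 0.1))
  expect_equal(nrow(suppressMessages(node_split_all(star))), 0L)
})

test_that("node splitting handles multi-arm designs via the GLS", {
  net <- nma_network(data.frame(
    study_id = c("m", "m", "s2", "s3", "s4"),
    treat_ref = c("A", "A", "A", "B", "A"),
    treat_alt = c("B", "C", "B", "C", "C"),
    effect = c(0.15, 0.3, 0.05, 0.2, 0.25), se = 0.1,
    shared_arm_variance = c(0.004, 0.004, NA, NA, NA)))
  ns <- node_split(net, c("A", "B"))
  # direct pools the two-arm design and the three-arm block estimate
  expect_true(is.finite(ns$z))
  expect_equal(ns$difference, ns$direct - ns$indirect, tolerance = 1e-10)
  # detaching both direct designs leaves the B:C + A:C indirect path
  expect_setequal(ns$detached_designs, c("A:B", "A:B:C"))
})
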