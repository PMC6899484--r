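test_that("eligibility excludes bridges and acyclic designs", {
  expect_setequal(eligible_designs(triangle_network(0, 0, 0)),
                  c("A:B", "A:C", "B:C"))

  star <- nma_network(data.frame(study_id = paste0("s", 1:3),
                                 treat_ref = "A",
                                 treat_alt = c("B", "C", "D"),
                                 effect = 0, se = 0.1))
  expect_warning(el <- eligible_designs(star), "loop")
  expect_length(el, 0)

  pendant <- nma_network(data.frame(study_id = paste0("s", 1:4),
                                    treat_ref = c("A", "A", "B", "C"),
                                    treat_alt = c("B", "C", "C", "D"),
                                    effect = 0, se = 0.1))
  expect_setequal(eligible_designs(pendant), c("A:B", "A:C", "B:C"))

  # a three-arm design shares its edges with a loop and stays eligible
  multi <- nma_network(data.frame(
    study_id = c("m", "m", "s2", "s3"),
    treat_ref = c("A", "A", "A", "B"),
    treat_alt = c("B", "C", "B", "C"),
    effect = 0, se = 0.1, shared_arm_variance = c(0.004, 0.004, NA, NA)))
  expect_true("A:B:C" %in% eligible_designs(multi))
})

test_that("detachment fits the detached design exactly", {
  net <- triangle_network(0.2, 0.9, 0.1, 0.1, 0.15, 0.2)
  fit <- nma_fit(net)
  af <- detach_design(fit, "A:B")
  idx <- fit$row_index[["A:B"]]
  expect_lt(max(abs((fit$y - af$fitted)[idx])), 1e-10)
  # with the only indirect path gone, AC network estimate = AC direct
  qdet <- q_inconsistency(af)$per_design
  expect_equal(unname(qdet[["A:C"]]), 0, tolerance = 1e-10)

  # detaching AC itself leaves the indirect evidence for AC
  af2 <- detach_design(fit, "A:C")
  ind <- 0.2 + 0.1
  L <- af2$basic_params
  expect_equal(unname(L["C"]), ind, tolerance = 1e-10)

  # detachment of an ineligible design errors
  star <- nma_network(data.frame(study_id = paste0("s", 1:3),
                                 treat_ref = "A", treat_alt = c("B", "C", "D"),
                                 effect = 0, se = 0.1))
  sfit <- nma_fit(star)
  expect_warning(expect_error(detach_design(sfit, "A:B"), "not eligible"))
})

test_that("three-arm design detachment adds t - 1 columns", {
  net <- nma_network(data.frame(
    study_id = c("m", "m", "s2", "s3", "s4"),
    treat_ref = c("A", "A", "A", "B", "A"),
    treat_alt = c("B", "C", "B", "C", "C"),
    effect = c(0.1, 0.2, 0.1, 0.1, 0.2), se = 0.1,
    shared_arm_variance = c(0.004, 0.004, NA, NA, NA)))
  fit <- nma_fit(net)
  af <- detach_design(fit, "A:B:C")
  expect_equal(ncol(af$X) - ncol(fit$X), 2L)
})

test_that("triangle net heat matrix equals the closed forms", {
  set.seed(67)
  for (i in 1:10) {
    v <- random_triangle_values()
    net <- triangle_network(v$theta[1], v$theta[2], v$theta[3],
                            sqrt(v$s2[1]), sqrt(v$s2[2]), sqrt(v$s2[3]))
    nh <- net_heat(net)
    ti <- triangle_inputs(v$theta[1], v$theta[2], v$theta[3],
                          v$s2[1], v$s2[2], v$s2[3])
    # off-diagonal row A:C: detached contribution is zero, so the entry is
    # the baseline contribution, matching the closed form
    expect_equal(nh$q_diff["A:C", "A:B"], triangle_qdiff_offdiag(ti),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(nh$q_diff["A:C", "B:C"], triangle_qdiff_offdiag(ti),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(nh$q_inc_detached["A:C", "A:B"], 0, tolerance = 1e-10,
                 ignore_attr = TRUE)
    # diagonal difference (own design detached) matches the negative form
    diag_diff <- nh$q_inc["A:C"] - nh$q_inc_detached["A:C", "A:C"]
    expect_equal(unname(diag_diff), triangle_qdiff_diag(ti), tolerance = 1e-8)
    # display diagonal carries the baseline contribution
    expect_equal(nh$q_diff["A:C", "A:C"], nh$q_inc[["A:C"]],
                 ignore_attr = TRUE)
  }
})

test_that("column sums track the total drop in Q_inc upon detachment", {
  net <- simulate_radial_network(sim_config(), k = 4, seed = 17)
  fit <- nma_fit(net)
  nh <- net_heat(net, fit)
  q_inc_total <- q_inconsistency(fit)$q_inc
  for (d in nh$designs_included) {
    diffs <- nh$q_inc - nh$q_inc_detached[, d]
    expect_equal(sum(diffs), q_inc_total - sum(nh$q_inc_detached[, d]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("hat contributions quantify information flow", {
  # equal-variance triangle: row A:C gets 2/3 from its own design and 1/3
  # from each leg of the indirect path (frozen from the projection algebra)
  nh <- net_heat(triangle_network(0.1, 0.5, 0.2))
  expect_equal(unname(nh$hat_abs["A:C", c("A:B", "A:C", "B:C")]),
               c(1 / 3, 2 / 3, 1 / 3), tolerance = 1e-10)

  # a design with overwhelming precision dominates its own row
  nh2 <- net_heat(triangle_network(0.1, 0.5, 0.2,
                                   se_ab = 0.1, se_ac = 1e-4, se_bc = 0.1))
  expect_gt(nh2$hat_abs["A:C", "A:C"], 0.999)

  # rows ordered by descending diagonal
  expect_true(all(diff(diag(nh$q_diff)) <= 1e-12))
})

test_that("net heat matrix round-trips through the long-format CSV", {
  nh <- net_heat(lung_network())
  path <- tempfile(fileext = ".csv")
  render_net_heat(nh, path)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(nrow(back), 9L)
  for (i in seq_len(nrow(back))) {
    expect_equal(back$q_diff[i],
                 nh$q_diff[back$row_design[i], back$col_design[i]],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("plot renders to file for ordinary and extreme matrices", {
  nh <- net_heat(lung_network())
  f <- tempfile(fileext = ".png")
  plot(nh, path = f)
  expect_true(file.size(f) > 0)
  # saturated matrix (entries beyond the clip) still renders
  nh2 <- net_heat(triangle_network(0, 5, 0, 0.05, 0.05, 0.05))
  expect_gt(max(nh2$q_diff), 8)
  f2 <- tempfile(fileext = ".svg")
  plot(nh2, path = f2)
  expect_true(file.size(f2) > 0)
})
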