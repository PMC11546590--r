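test_that("generation is deterministic under the seed and honors the design", {
  cond <- sim_condition(2, "overlap", 5, "spread", abilities = "equal",
                        n_persons = 50)
  g1 <- sim_generate(cond, seed = 123)
  g2 <- sim_generate(cond, seed = 123)
  expect_identical(g1$data$records, g2$data$records)
  expect_identical(g1$truth, g2$truth)
  g3 <- sim_generate(cond, seed = 124)
  expect_false(identical(g1$data$records, g3$data$records))

  # complete data: every person answers every item
  expect_equal(nrow(g1$data$records), g1$data$N * g1$data$L)
  expect_equal(g1$data$L, 2 * (10 + 5))
  # with zero misspecification, cluster copies share the true difficulty
  for (q in unique(g1$clusters$cluster_id)) {
    m <- g1$clusters$item_id[g1$clusters$cluster_id == q]
    expect_equal(diff(range(g1$truth$delta_true[match(m, g1$truth$item_id)])), 0)
  }
  # misspecification shifts only the non-reference copies
  cond_d <- sim_condition(2, "overlap", 5, "spread", delta_shift = 0.8,
                          abilities = "equal", n_persons = 50)
  gd <- sim_generate(cond_d, seed = 123)
  d1 <- gd$truth$delta_true[match("eq01_instr1", gd$truth$item_id)]
  d2 <- gd$truth$delta_true[match("eq01_instr2", gd$truth$item_id)]
  expect_equal(d2 - d1, 0.8)
})

test_that("unique difficulties stay in range; placements sit where stated", {
  cond <- sim_condition(2, "close", 2, "one_instrument", n_persons = 20)
  g <- sim_generate(cond, seed = 3)
  u1 <- g$truth$delta_true[grepl("^instr1_item", g$truth$item_id)]
  u2 <- g$truth$delta_true[grepl("^instr2_item", g$truth$item_id)]
  expect_true(all(u1 >= -3 & u1 <= -0.1))
  expect_true(all(u2 >= 0.1 & u2 <= 3))
  eq <- g$truth$delta_true[grepl("^eq\\d+_instr1", g$truth$item_id)]
  expect_true(all(eq >= -3 & eq <= -0.1))  # within instrument 1's range

  cond_c <- sim_condition(2, "close", 1, "center", n_persons = 20)
  gc_ <- sim_generate(cond_c, seed = 3)
  eq_c <- gc_$truth$delta_true[gc_$truth$item_id == "eq01_instr1"]
  expect_equal(eq_c, 0)  # midpoint of the union of close ranges

  cond_e <- sim_condition(2, "close", 1, "extreme", n_persons = 20)
  ge <- sim_generate(cond_e, seed = 3)
  eq_e <- ge$truth$delta_true[ge$truth$item_id == "eq01_instr1"]
  expect_lt(eq_e, -2.5)  # at the outer edge of instrument 1's range
})

test_that("a mid-scale item passes about half the time under equal abilities", {
  cond <- sim_condition(2, "close", 1, "center", abilities = "equal",
                        n_persons = 2000)
  g <- sim_generate(cond, seed = 29)
  rec <- g$data$records
  rate <- mean(rec$score[rec$item_id == "eq01_instr1"])
  expect_equal(rate, 0.5, tolerance = 0.03)
})

test_that("misalignment recovers identity, shifts, and tolerates jitter", {
  delta <- c(seq(-2, 0, length.out = 6), seq(0, 2, length.out = 6))
  instr <- rep(c("A", "B"), each = 6)
  # identity
  m0 <- misalignment(delta, delta, instr)
  expect_equal(m0$gamma, 0, tolerance = 1e-12)
  expect_equal(m0$rho, 1)
  expect_equal(m0$b, 1)
  expect_equal(m0$c, 0, tolerance = 1e-12)
  # instrument B shifted down by 4 -> gamma = 4
  est <- ifelse(instr == "B", delta - 4, delta)
  m1 <- misalignment(delta, est, instr)
  expect_equal(m1$gamma, 4, tolerance = 1e-10)
  # small jitter, no shift -> gamma near 0, rho near 1
  set.seed(31)
  m2 <- misalignment(delta, delta + rnorm(12, 0, 0.1), instr)
  expect_lt(abs(m2$gamma), 0.25)
  expect_gt(m2$rho, 0.98)
  # three instruments, block shifts linear in the index: estimates shifted by
  # -2k make true = est + 2k an exact representation, so gamma = 2 exactly
  instr3 <- rep(c("A", "B", "C"), each = 4)
  k3 <- rep(0:2, each = 4)
  m3 <- misalignment(delta, delta - 2 * k3, instr3)
  expect_equal(m3$gamma, 2, tolerance = 1e-10)
  expect_equal(m3$b, 1, tolerance = 1e-10)
  expect_equal(unname(m3$gamma_by_instrument), c(2, 4), tolerance = 1e-8)
  expect_error(misalignment(delta[1:3], delta[1:3], c("A", "A", "B")),
               ">= 2")
})

test_that("reference truth from complete data tracks generating values", {
  cond <- sim_condition(2, "overlap", 2, "spread", abilities = "equal",
                        n_persons = 1000)
  g <- sim_generate(cond, seed = 37)
  ref <- reference_truth(g)
  truth <- g$truth$delta_true[match(ref$item_id, g$truth$item_id)]
  expect_gt(cor(ref$difficulty, truth), 0.99)
})

test_that("run_cell aligns the constrained model and degrades the free one", {
  cond <- sim_condition(2, "close", 5, "spread", abilities = "different",
                        n_persons = 600)
  cell <- run_cell(cond, replicates = 3, seed = 41)
  s <- cell$summary
  expect_equal(nrow(s), 2)
  con <- s[s$model == "constrained", ]
  unc <- s[s$model == "unconstrained", ]
  expect_gt(con$rho, 0.99)
  expect_lt(abs(con$gamma), 0.25)
  expect_gt(unc$abs_gamma, 1)
  expect_gt(con$rho, unc$rho)
})

test_that("run_design marginals aggregate the cells", {
  grid <- data.frame(n_instruments = 2, overlap = "overlap", n_equates = 2,
                     placement = "spread", abilities = "equal")
  des <- run_design(grid, replicates = 2, seed = 43, n_persons = 300)
  expect_equal(nrow(des$cells), 2)
  # a one-cell grid's marginal equals the cell
  for (mod in c("constrained", "unconstrained")) {
    expect_equal(des$marginal$rho[des$marginal$model == mod],
                 des$cells$rho[des$cells$model == mod])
  }
})

test_that("breakpoint sweep finds no crossover when anchors are correct", {
  cond <- sim_condition(2, "close", 2, "spread", abilities = "different",
                        n_persons = 400)
  bp <- misfit_breakpoint(cond, deltas = c(0, 0.4), replicates = 2, seed = 47)
  expect_true(is.infinite(bp$breakpoint))
  # constrained |gamma| grows with misspecification
  con <- bp$sweep[bp$sweep$model == "constrained", ]
  expect_gt(con$abs_gamma[con$delta_shift == 0.4],
            con$abs_gamma[con$delta_shift == 0])
})
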