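test_that("pass_probability follows the logistic closed forms", {
  expect_equal(pass_probability(0, 0), 0.5)
  expect_equal(pass_probability(1.3, 1.3), 0.5)
  expect_equal(pass_probability(log(9), 0), 0.9)
  expect_equal(pass_probability(0, log(9)), 0.1)
  # strictly monotone in both arguments
  b <- seq(-4, 4, 0.5)
  expect_true(all(diff(pass_probability(b, 0)) > 0))
  expect_true(all(diff(pass_probability(0, b)) < 0))
})

test_that("pooled_difficulty is the respondent-weighted average", {
  expect_equal(pooled_difficulty(0.7, 123), 0.7)
  expect_equal(pooled_difficulty(c(-1, 1), c(50, 50)), 0)
  expect_equal(pooled_difficulty(c(-1, 2), c(100, 300)), 1.25)
  expect_error(pooled_difficulty(numeric(0), numeric(0)), "empty")
  expect_error(pooled_difficulty(c(1, 2), c(0, 0)), "weights")
})

test_that("engine difficulties match the brute-force grid oracle", {
  # enumerable 3 x 6 toy
  fx <- make_fixture("tiny-complete")
  fit <- rasch_fit(fx$data, tol = 1e-10, abilities = "none")
  oracle <- grid_oracle_3item(win_matrix(fx$data))
  expect_equal(unname(coef(fit)), oracle, tolerance = 1e-3)

  # a larger random 3-item design
  sm <- sim_small(n_persons = 200, delta = c(-0.8, 0.2, 0.6), seed = 7)
  fit2 <- rasch_fit(sm$data, tol = 1e-10, abilities = "none")
  oracle2 <- grid_oracle_3item(win_matrix(sm$data))
  expect_equal(unname(coef(fit2)), oracle2, tolerance = 1e-3)
})

test_that("difficulties are identified to mean zero and recover the truth", {
  sm <- sim_small(n_persons = 1000, delta = seq(-2, 2, length.out = 10),
                  seed = 11)
  fit <- rasch_fit(sm$data, abilities = "none")
  expect_equal(mean(coef(fit)), 0, tolerance = 1e-8)
  expect_gt(cor(coef(fit), sm$delta), 0.99)
})

test_that("a vacuous constraint reproduces the unconstrained estimate", {
  # two identical items administered to the same persons
  set.seed(4)
  beta <- rnorm(400)
  delta <- c(-0.5, 0.3, 0.3, 1)
  ids <- c("i1", "i2a", "i2b", "i3")
  X <- matrix(as.integer(runif(1600) < plogis(outer(beta, delta, "-"))),
              400, dimnames = list(sprintf("p%03d", 1:400), ids))
  rec <- data.frame(person_id = rep(rownames(X), 4),
                    item_id = rep(ids, each = 400),
                    score = as.vector(X), instrument = "A")
  data <- response_matrix(rec)
  cl <- equate_clusters(data.frame(cluster_id = "q", item_id = c("i2a", "i2b"),
                                   active = TRUE))
  con <- rasch_fit(data, cl, constrained = TRUE, abilities = "none")
  expect_equal(coef(con)[["i2a"]], coef(con)[["i2b"]])
  unc <- rasch_fit(data, cl, constrained = FALSE, abilities = "none")
  # pooled estimate sits near the average of the two free ones
  expect_lt(abs(coef(con)[["i2a"]] - mean(coef(unc)[c("i2a", "i2b")])), 0.05)
  expect_gte(coef(con)[["i2a"]], min(coef(unc)[c("i2a", "i2b")]))
  expect_lte(coef(con)[["i2a"]], max(coef(unc)[c("i2a", "i2b")]))
})

test_that("active-cluster difficulty spread is exactly zero after fitting", {
  fx <- make_fixture("dif-cluster", seed = 5, n_persons = 300)
  fit <- rasch_fit(fx$data, fx$clusters, abilities = "none")
  for (q in unique(fx$clusters$cluster_id)) {
    members <- fx$clusters$item_id[fx$clusters$cluster_id == q]
    d <- coef(fit)[members]
    expect_equal(max(d) - min(d), 0)
  }
})

test_that("difficulty differences do not depend on the sample's abilities", {
  delta <- seq(-1.5, 1.5, length.out = 8)
  lo <- sim_small(1500, delta, mu = -1, seed = 21, prefix = "L")
  hi <- sim_small(1500, delta, mu = +1, seed = 22, prefix = "H")
  d_lo <- coef(rasch_fit(lo$data, abilities = "none"))
  d_hi <- coef(rasch_fit(hi$data, abilities = "none"))
  diffs_lo <- outer(d_lo, d_lo, "-")
  diffs_hi <- outer(d_hi, d_hi, "-")
  # sampling bound: each difficulty has se ~ sqrt(2 / (n w)) with w down to
  # ~0.07 for the most off-target item/sample pairs (se ~ 0.1 per estimate);
  # a max over 28 pair differences across two samples stays within ~4 sd
  expect_lt(max(abs(diffs_lo - diffs_hi)), 0.6)
  expect_gt(cor(as.vector(diffs_lo), as.vector(diffs_hi)), 0.97)
})

test_that("raising responses of an item lowers its estimated difficulty", {
  sm <- sim_small(n_persons = 400, seed = 31)
  fit0 <- rasch_fit(sm$data, abilities = "none")
  rec <- sm$data$records
  zeros <- which(rec$item_id == "A_it03" & rec$score == 0)
  rec$score[zeros[1:50]] <- 1L
  fit1 <- rasch_fit(response_matrix(rec), abilities = "none")
  expect_lt(coef(fit1)[["A_it03"]], coef(fit0)[["A_it03"]])
})

test_that("estimates are invariant to person and item relabeling", {
  sm <- sim_small(n_persons = 250, seed = 41)
  rec <- sm$data$records
  # permute rows and rename persons/items bijectively
  rec <- rec[sample.int(nrow(rec)), ]
  rec$person_id <- paste0("zz_", rec$person_id)
  map <- setNames(sprintf("renamed%02d", seq_len(6)),
                  sort(unique(rec$item_id)))
  rec$item_id <- unname(map[rec$item_id])
  fit0 <- coef(rasch_fit(sm$data, abilities = "none"))
  fit1 <- coef(rasch_fit(response_matrix(rec), abilities = "none"))
  expect_equal(unname(fit1[map]), unname(fit0), tolerance = 1e-9)
})

test_that("degenerate items are excluded with a warning", {
  sm <- sim_small(n_persons = 60, seed = 51)
  rec <- sm$data$records
  rec$score[rec$item_id == "A_it01"] <- 1L  # all-pass item
  expect_warning(fit <- rasch_fit(response_matrix(rec), abilities = "none"),
                 "excluding")
  expect_equal(fit$excluded, "A_it01")
  expect_false("A_it01" %in% names(coef(fit)))
})

test_that("constrained fitting refuses a disconnected design", {
  fx <- make_fixture("two-instrument-bridge", seed = 6, n_persons = 40)
  off <- fx$clusters
  off$active <- FALSE
  expect_error(rasch_fit(fx$data |> to_incomplete_design(
    setNames(ifelse(startsWith(fx$data$persons, "A"), "A", "B"),
             fx$data$persons)), off, constrained = TRUE),
    "single linked component")
})
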