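test_that("standardized residuals follow their closed forms", {
  rec <- data.frame(person_id = c("p1", "p1", "p2"),
                    item_id = c("a", "b", "a"),
                    score = c(1L, 0L, 1L), instrument = "A")
  data <- response_matrix(rec)
  key <- raschlink:::new_key(data.frame(
    item_id = c("a", "b"), instrument = "A",
    difficulty = 0, cluster_id = NA_character_))
  ab <- data.frame(person_id = c("p1", "p2"), beta = c(0, qlogis(0.9)))
  res <- rasch_residuals(data, key, ab)
  # x=1, pi=0.5 -> z = 1, W = 0.25
  expect_equal(res$z["p1", "a"], 1)
  expect_equal(res$W["p1", "a"], 0.25)
  # x=0, pi=0.5 -> z = -1 by sign symmetry
  expect_equal(res$z["p1", "b"], -1)
  # x=1, pi=0.9 -> z = 0.1/sqrt(0.09) = 1/3, W = 0.09
  expect_equal(res$z["p2", "a"], 1 / 3)
  expect_equal(res$W["p2", "a"], 0.09)
  # unobserved cells stay NA
  expect_true(is.na(res$z["p2", "b"]))
  # missing key item errors
  expect_error(rasch_residuals(
    data, raschlink:::new_key(key[key$item_id == "a", ]), ab), "missing from key")
})

test_that("outfit is exactly 1 on a deterministic +-1 residual pattern", {
  # all pi = 0.5 and scores split half/half per item -> every z in {-1, 1}
  rec <- expand.grid(person_id = sprintf("p%d", 1:10),
                     item_id = c("a", "b"), stringsAsFactors = FALSE)
  rec$score <- rep_len(c(0L, 1L), nrow(rec))
  rec$instrument <- "A"
  data <- response_matrix(rec)
  key <- raschlink:::new_key(data.frame(
    item_id = c("a", "b"), instrument = "A", difficulty = 0,
    cluster_id = NA_character_))
  ab <- data.frame(person_id = sprintf("p%d", 1:10), beta = 0)
  res <- rasch_residuals(data, key, ab)
  f <- item_fit(res)
  expect_equal(f$outfit, c(1, 1))
  expect_equal(f$infit, c(1, 1))
  p <- person_fit(res)
  expect_equal(p$outfit, rep(1, 10))
})

test_that("well-fitting simulated data yield item fit near 1, noise above 1.5", {
  # Monte-Carlo null: against the generating abilities and difficulties of a
  # moderate sample, every conforming item's mean square concentrates near 1
  sm <- sim_small(n_persons = 1000, delta = seq(-2, 2, length.out = 10),
                  seed = 8)
  true_key <- raschlink:::new_key(data.frame(
    item_id = names(sm$delta), instrument = "A",
    difficulty = unname(sm$delta), cluster_id = NA_character_))
  res_null <- rasch_residuals(
    sm$data, true_key,
    data.frame(person_id = sm$data$persons,
               beta = sm$beta[match(sm$data$persons,
                                    sprintf("A_p%04d", seq_along(sm$beta)))]))
  f_null <- item_fit(res_null)
  expect_true(all(f_null$outfit > 0.8 & f_null$outfit < 1.2))
  expect_true(all(f_null$infit > 0.8 & f_null$infit < 1.2))

  # fitted model: the ability-independent coin-flip item stands out
  fx <- make_fixture("noise-item", seed = 8, n_persons = 1000)
  fit <- rasch_fit(fx$data)
  f <- item_fit(residuals(fit))
  expect_gt(f$outfit[f$item_id == "noise"], 1.5)
  expect_true(all(f$outfit[f$item_id != "noise"] < 1.2))
})

test_that("equate fit reduces to item fit for singletons and averages members", {
  fx <- make_fixture("two-instrument-bridge", seed = 9, n_persons = 400)
  fit <- rasch_fit(fx$data, fx$clusters)
  res <- residuals(fit)
  f <- item_fit(res)
  # singleton cluster: equals the member's own statistics exactly
  singleton <- equate_clusters(data.frame(
    cluster_id = "s", item_id = "A_item1", active = TRUE))
  ef1 <- equate_fit(res, singleton)
  expect_equal(ef1$outfit, f$outfit[f$item_id == "A_item1"])
  expect_equal(ef1$infit, f$infit[f$item_id == "A_item1"])
  # two members: the mean of the members' item statistics (direct double-sum)
  ef2 <- equate_fit(res, fx$clusters)
  members <- fx$clusters$item_id
  expect_equal(ef2$outfit, mean(f$outfit[match(members, f$item_id)]))
  z2 <- res$z[, members]^2
  direct_u <- sum(colMeans(z2, na.rm = TRUE)) / length(members)
  expect_equal(ef2$outfit, direct_u)
  direct_v <- mean(colSums(res$W[, members] * z2, na.rm = TRUE) /
                     colSums(res$W[, members], na.rm = TRUE))
  expect_equal(ef2$infit, direct_v)
  # a well-specified cluster fits below the 1.5 cutoff
  expect_lt(ef2$outfit, 1.5)
  expect_lt(ef2$infit, 1.5)
  expect_error(equate_fit(res, equate_clusters(
    data.frame(cluster_id = character(0), item_id = character(0),
               active = logical(0)))), "no clusters")
})

test_that("purification removes exactly the injected noise item", {
  fx <- make_fixture("noise-item", seed = 10, n_persons = 1000)
  pur <- purify(fx$data, threshold = 1.5)
  expect_equal(pur$removed$item_id, "noise")
  expect_equal(sort(pur$kept), sort(setdiff(fx$data$items$item_id, "noise")))
  # idempotent: a second pass removes nothing
  pur2 <- purify(response_matrix(
    fx$data$records[fx$data$records$item_id != "noise", ]), threshold = 1.5)
  expect_equal(nrow(pur2$removed), 0)
  # threshold = Inf is the identity
  pur3 <- purify(fx$data, threshold = Inf)
  expect_equal(nrow(pur3$removed), 0)
  expect_equal(sort(pur3$kept), sort(fx$data$items$item_id))
})
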