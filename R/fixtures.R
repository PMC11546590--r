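#' Deterministic test fixtures
#'
#' Small synthetic datasets with known properties, generated in code (never
#' stored as files) and bit-identical under the same seed:
#'
#' * `"tiny-complete"`: 3 items x 6 persons (18 records), every pattern
#'   enumerable by hand; no randomness.
#' * `"two-instrument-bridge"`: two instruments with disjoint respondent
#'   samples linked only by one equate cluster; with the cluster inactive the
#'   design falls apart into 2 components.
#' * `"noise-item"`: 10 items following the Rasch model in an ability-
#'   heterogeneous sample (abilities N(0, 2)), plus one item whose responses
#'   are coin flips independent of ability (the classic misfit injection for
#'   purification tests; the wide ability spread is what makes an
#'   ability-independent item stand out in the residuals).
#' * `"dif-cluster"`: two instruments bridged by two clusters, one clean and
#'   one whose two members truly differ by 1 logit although calibrated as a
#'   single cluster (uniform DIF injection).
#'
#' @param name fixture name (see above).
#' @param seed integer seed for the stochastic fixtures.
#' @param n_persons sample size per instrument for the stochastic fixtures.
#' @return list with `data` ([response_matrix]), `clusters` (or `NULL`) and
#'   `truth` (named list of known properties: true difficulties, injected
#'   defects).
#' @export
make_fixture <- function(name, seed = 1L, n_persons = 1000L) {
  switch(name,
    "tiny-complete" = fixture_tiny(),
    "two-instrument-bridge" = fixture_bridge(seed, n_persons),
    "noise-item" = fixture_noise(seed, n_persons),
    "dif-cluster" = fixture_dif(seed, n_persons),
    stop("unknown fixture: ", name)
  )
}

fixture_tiny <- function() {
  # 6 persons x 3 items, fixed patterns; item1 easiest, item3 hardest
  patterns <- rbind(
    c(1, 1, 0), c(1, 0, 0), c(1, 1, 1),
    c(0, 1, 0), c(1, 0, 1), c(0, 0, 1)
  )
  rownames(patterns) <- sprintf("p%d", 1:6)
  colnames(patterns) <- sprintf("item%d", 1:3)
  data <- rm_from_wide(patterns,
                       stats::setNames(rep("A", 3), colnames(patterns)))
  list(data = data, clusters = NULL,
       truth = list(n_records = 18L, pass_counts = colSums(patterns)))
}

fixture_bridge <- function(seed, n_persons) {
  set.seed(seed)
  delta_a <- seq(-2, 0.5, length.out = 6)
  delta_b <- seq(-0.5, 2, length.out = 6)
  eq_delta <- 0
  gen_block <- function(prefix, mu, deltas, eq_id) {
    beta <- stats::rnorm(n_persons, mu, 1)
    delta <- c(deltas, eq_delta)
    ids <- c(sprintf("%s_item%d", prefix, seq_along(deltas)),
             paste0("eq1_", prefix))
    P <- pass_probability(matrix(beta, n_persons, length(delta)),
                          matrix(delta, n_persons, length(delta), byrow = TRUE))
    X <- matrix(as.integer(stats::runif(length(P)) < P), n_persons,
                dimnames = list(sprintf("%s_p%04d", prefix, seq_len(n_persons)),
                                ids))
    X
  }
  Xa <- gen_block("A", -0.5, delta_a, "eq1")
  Xb <- gen_block("B", 0.5, delta_b, "eq1")
  X <- matrix(NA_integer_, 2 * n_persons, ncol(Xa) + ncol(Xb),
              dimnames = list(c(rownames(Xa), rownames(Xb)),
                              c(colnames(Xa), colnames(Xb))))
  X[rownames(Xa), colnames(Xa)] <- Xa
  X[rownames(Xb), colnames(Xb)] <- Xb
  instrument <- stats::setNames(rep(c("A", "B"), each = ncol(Xa)), colnames(X))
  clusters <- equate_clusters(data.frame(
    cluster_id = "eq1", item_id = c("eq1_A", "eq1_B"), active = TRUE,
    stringsAsFactors = FALSE))
  list(data = rm_from_wide(X, instrument), clusters = clusters,
       truth = list(delta = stats::setNames(
         c(delta_a, eq_delta, delta_b, eq_delta), colnames(X))))
}

fixture_noise <- function(seed, n_persons) {
  set.seed(seed)
  delta <- seq(-2, 2, length.out = 10)
  beta <- stats::rnorm(n_persons, 0, 2)
  ids <- c(sprintf("item%02d", 1:10), "noise")
  P <- pass_probability(matrix(beta, n_persons, 10),
                        matrix(delta, n_persons, 10, byrow = TRUE))
  X <- cbind(matrix(as.integer(stats::runif(length(P)) < P), n_persons),
             as.integer(stats::runif(n_persons) < 0.5))
  dimnames(X) <- list(sprintf("p%04d", seq_len(n_persons)), ids)
  list(data = rm_from_wide(X, stats::setNames(rep("A", 11), ids)),
       clusters = NULL,
       truth = list(delta = stats::setNames(c(delta, NA), ids),
                    beta = stats::setNames(beta, rownames(X)),
                    noise_item = "noise"))
}

fixture_dif <- function(seed, n_persons) {
  set.seed(seed)
  delta_a <- seq(-2, 1, length.out = 8)
  delta_b <- seq(-1, 2, length.out = 8)
  # clean cluster: both copies at 0; dif cluster: copies at -0.5 / +0.5
  gen_block <- function(prefix, mu, deltas, eq_deltas) {
    beta <- stats::rnorm(n_persons, mu, 1)
    delta <- c(deltas, eq_deltas)
    ids <- c(sprintf("%s_item%d", prefix, seq_along(deltas)),
             paste0(c("eq_clean_", "eq_dif_"), prefix))
    P <- pass_probability(matrix(beta, n_persons, length(delta)),
                          matrix(delta, n_persons, length(delta), byrow = TRUE))
    matrix(as.integer(stats::runif(length(P)) < P), n_persons,
           dimnames = list(sprintf("%s_p%04d", prefix, seq_len(n_persons)), ids))
  }
  Xa <- gen_block("A", -0.5, delta_a, c(0, -0.5))
  Xb <- gen_block("B", 0.5, delta_b, c(0, 0.5))
  X <- matrix(NA_integer_, 2 * n_persons, ncol(Xa) + ncol(Xb),
              dimnames = list(c(rownames(Xa), rownames(Xb)),
                              c(colnames(Xa), colnames(Xb))))
  X[rownames(Xa), colnames(Xa)] <- Xa
  X[rownames(Xb), colnames(Xb)] <- Xb
  instrument <- stats::setNames(rep(c("A", "B"), each = ncol(Xa)), colnames(X))
  clusters <- equate_clusters(data.frame(
    cluster_id = c("eq_clean", "eq_clean", "eq_dif", "eq_dif"),
    item_id = c("eq_clean_A", "eq_clean_B", "eq_dif_A", "eq_dif_B"),
    active = TRUE, stringsAsFactors = FALSE))
  list(data = rm_from_wide(X, instrument), clusters = clusters,
       truth = list(dif_cluster = "eq_dif", dif_size = 1,
                    clean_cluster = "eq_clean"))
}
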