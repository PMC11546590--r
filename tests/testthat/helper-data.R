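# small simulated dataset: one instrument, known difficulties
sim_small <- function(n_persons = 500, delta = seq(-1.5, 1.5, length.out = 6),
                      mu = 0, seed = 1, prefix = "A") {
  set.seed(seed)
  beta <- rnorm(n_persons, mu, 1)
  ids <- sprintf("%s_it%02d", prefix, seq_along(delta))
  P <- plogis(outer(beta, delta, "-"))
  X <- matrix(as.integer(runif(length(P)) < P), n_persons,
              dimnames = list(sprintf("%s_p%04d", prefix, seq_len(n_persons)),
                              ids))
  list(X = X, beta = beta, delta = setNames(delta, ids),
       data = response_matrix(data.frame(
         person_id = rep(rownames(X), ncol(X)),
         item_id = rep(ids, each = n_persons),
         score = as.vector(X),
         instrument = prefix, stringsAsFactors = FALSE)))
}

# pairwise conditional log-likelihood for a win-count matrix, used by the
# brute-force grid oracle
pairwise_loglik <- function(delta, nij) {
  eps <- exp(-delta)
  ll <- 0
  L <- length(delta)
  for (i in seq_len(L - 1)) {
    for (j in seq(i + 1, L)) {
      denom <- eps[i] + eps[j]
      if (nij[i, j] > 0) ll <- ll + nij[i, j] * log(eps[i] / denom)
      if (nij[j, i] > 0) ll <- ll + nij[j, i] * log(eps[j] / denom)
    }
  }
  ll
}

win_matrix <- function(data) {
  X <- matrix(NA_integer_, data$N, data$L,
              dimnames = list(data$persons, data$items$item_id))
  X[cbind(match(data$records$person_id, data$persons),
          match(data$records$item_id, data$items$item_id))] <- data$records$score
  X1 <- (!is.na(X) & X == 1) + 0
  X0 <- (!is.na(X) & X == 0) + 0
  nij <- crossprod(X1, X0)
  diag(nij) <- 0
  nij
}

# brute-force grid maximization over the identified space of a 3-item design
# (delta3 = -delta1 - delta2), refined to fine resolution
grid_oracle_3item <- function(nij, lim = 4) {
  centre <- c(0, 0)
  width <- lim
  for (pass in 1:6) {
    g <- seq(-width, width, length.out = 41)
    vals <- expand.grid(d1 = centre[1] + g, d2 = centre[2] + g)
    ll <- mapply(function(d1, d2) pairwise_loglik(c(d1, d2, -d1 - d2), nij),
                 vals$d1, vals$d2)
    centre <- as.numeric(vals[which.max(ll), ])
    width <- width / 10
  }
  c(centre, -sum(centre))
}
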