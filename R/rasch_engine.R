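#' Rasch pass probability
#'
#' Probability that a person of ability `beta` passes an item of difficulty
#' `delta` under the dichotomous Rasch model,
#' \eqn{\pi = \exp(\beta-\delta)/(1+\exp(\beta-\delta))}. Vectorized with
#' recycling.
#'
#' @param beta person ability in logits.
#' @param delta item difficulty in logits.
#' @return probability in (0, 1), saturating smoothly for extreme differences.
#' @examples
#' pass_probability(0, 0)        # 0.5
#' pass_probability(log(9), 0)   # 0.9
#' @export
pass_probability <- function(beta, delta) {
  stats::plogis(beta - delta)
}

#' Pooled difficulty of an equate cluster
#'
#' The cluster difficulty is the respondent-weighted average of its members'
#' separate difficulty estimates,
#' \eqn{\hat\delta_q = \sum_i \hat\delta_i w_i / \sum_i w_i},
#' where \eqn{w_i} is the number of respondents of item \eqn{i}. During
#' constrained fitting every member estimate is replaced by this pooled value
#' after each iteration.
#'
#' @param estimates numeric vector of member difficulty estimates.
#' @param weights positive respondent counts, same length.
#' @return the pooled difficulty (scalar).
#' @export
pooled_difficulty <- function(estimates, weights) {
  if (length(estimates) == 0) stop("empty cluster")
  if (length(weights) != length(estimates)) stop("length mismatch")
  if (any(weights < 0) || sum(weights) <= 0) stop("weights must be positive")
  sum(estimates * weights) / sum(weights)
}

#' Fit the (constrained) Rasch model to multi-instrument data
#'
#' Estimates item difficulties by pairwise conditional estimation on the
#' item-pair win matrix (counts of persons passing item i while failing item
#' j), the natural estimator for incomplete multi-instrument designs because
#' it conditions out the person parameters and uses, for every item pair, only
#' the persons who answered both. When `constrained = TRUE`, after each
#' fixed-point iteration the difficulties of items in each *active* equate
#' cluster are replaced by their pooled value (see [pooled_difficulty()]), so
#' active clusters act as anchors bridging instruments.
#'
#' Identification: difficulties are centered to mean zero each iteration (the
#' Rasch scale has an arbitrary zero). The iteration starts from the centered
#' logit of each item's observed failure rate. Items whose observed responses
#' are all 0 or all 1 (or that never win/lose a pairwise comparison) carry no
#' information about their own difficulty and are excluded with a warning.
#'
#' @param data a [response_matrix].
#' @param clusters an [equate_clusters] definition or `NULL`.
#' @param constrained enforce active-cluster equality constraints? When `TRUE`
#'   the design must form a single linked component (see
#'   [validate_connectivity()]).
#' @param tol convergence tolerance: maximum absolute difficulty change
#'   between iterations.
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   last iterate in its `condition` data.
#' @param abilities `"wle"` to estimate person abilities (weighted likelihood,
#'   finite for perfect response patterns) from the final key, `"none"` to
#'   skip (faster; fit statistics and residuals then require scoring first).
#' @return An object of class `rasch_fit`: list with elements `key` (a
#'   `rasch_key`), `abilities` (data.frame `person_id`, `beta`, `se`,
#'   `n_items`, `flag`; `NULL` when `abilities = "none"`), `converged`,
#'   `n_iter`, `constraint_set` (active cluster ids), `excluded` (item ids
#'   dropped from calibration), `clusters`, and `data`.
#' @seealso [score_abilities()], [item_fit()], [equate_fit()], [dif_test()]
#' @examples
#' fx <- make_fixture("tiny-complete")
#' fit <- rasch_fit(fx$data)
#' coef(fit)
#' @export
rasch_fit <- function(data, clusters = NULL, constrained = TRUE,
                      tol = 1e-6, max_iter = 100000L,
                      abilities = c("wle", "none")) {
  stopifnot(inherits(data, "response_matrix"))
  abilities <- match.arg(abilities)
  if (!is.null(clusters)) check_clusters_against_data(data, clusters)
  if (constrained && !is.null(clusters)) {
    conn <- validate_connectivity(data, clusters)
    if (!conn$linked) {
      stop("constrained calibration requires a single linked component; found ",
           conn$n_components, " components")
    }
  }
  X <- rm_wide(data)
  eng <- pairwise_engine(
    X,
    cluster_map = if (constrained) cluster_members(clusters) else list(),
    tol = tol, max_iter = max_iter
  )
  items <- data$items[match(colnames(eng$X), data$items$item_id), , drop = FALSE]
  cl_of_item <- rep(NA_character_, nrow(items))
  if (!is.null(clusters)) {
    idx <- match(items$item_id, clusters$item_id)
    cl_of_item <- clusters$cluster_id[idx]
  }
  constraint_set <- if (constrained) names(cluster_members(clusters)) else character(0)
  meta <- list(
    date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    constrained = constrained,
    constraint_set = constraint_set,
    converged = eng$converged,
    n_iter = eng$n_iter,
    tol = tol,
    excluded = eng$excluded
  )
  key <- new_key(
    data.frame(item_id = items$item_id, instrument = items$instrument,
               difficulty = eng$delta, cluster_id = cl_of_item,
               stringsAsFactors = FALSE),
    meta = meta
  )
  ab <- NULL
  if (abilities == "wle") {
    ab <- score_abilities(data, key)
  }
  structure(
    list(key = key, abilities = ab, converged = eng$converged,
         n_iter = eng$n_iter, constraint_set = constraint_set,
         excluded = eng$excluded, clusters = clusters, constrained = constrained,
         free_delta = eng$free_delta, data = data, call = match.call()),
    class = "rasch_fit"
  )
}

# Core fixed-point solver on a wide 0/1/NA matrix.
# Maximizes the pairwise conditional likelihood: with eps_i = exp(-delta_i),
# P(i passed, j failed | exactly one of i,j passed) = eps_i / (eps_i + eps_j).
# Stationarity gives eps_i = r_i / sum_j N_ij/(eps_i+eps_j) with r_i the wins
# of i and N_ij the decided comparisons, iterated to a fixed point. For
# designs whose instruments are not linked, the between-block offset is not
# identified; the iteration then retains the offset implied by its pass-rate
# start (each block roughly centered relative to its own sample).
pairwise_engine <- function(X, cluster_map = list(), tol = 1e-6,
                            max_iter = 100000L) {
  obs <- !is.na(X)
  n1 <- colSums(X == 1, na.rm = TRUE)
  n_obs <- colSums(obs)
  degenerate <- n1 == 0 | n1 == n_obs
  X1 <- (!is.na(X) & X == 1) + 0
  X0 <- (!is.na(X) & X == 0) + 0
  nij <- crossprod(X1, X0)
  diag(nij) <- 0
  r <- rowSums(nij)
  l <- colSums(nij)
  no_info <- r == 0 | l == 0
  excluded <- colnames(X)[degenerate | no_info]
  if (length(excluded) > 0) {
    warning("excluding ", length(excluded),
            " item(s) with undetermined difficulty (all-0/all-1 or no ",
            "pairwise information): ",
            paste(utils::head(excluded, 8), collapse = ", "))
    keep <- !(degenerate | no_info)
    X <- X[, keep, drop = FALSE]
    obs <- obs[, keep, drop = FALSE]
    nij <- nij[keep, keep, drop = FALSE]
    r <- rowSums(nij)
    n1 <- n1[keep]; n_obs <- n_obs[keep]
    cluster_map <- lapply(cluster_map, intersect, colnames(X))
    cluster_map <- cluster_map[lengths(cluster_map) > 0]
  }
  if (ncol(X) < 2) stop("fewer than 2 calibratable items")
  Nij <- nij + t(nij)
  w <- n_obs
  names(w) <- colnames(X)
  cl_idx <- lapply(cluster_map, match, colnames(X))
  # start: centered logit failure rate
  delta <- stats::qlogis(1 - n1 / n_obs)
  delta <- delta - mean(delta)
  converged <- FALSE
  it <- 0L
  one_step <- function(delta) {
    eps <- exp(-delta)
    delta_new <- -log(r / rowSums(Nij / outer(eps, eps, "+")))
    for (m in cl_idx) {
      delta_new[m] <- pooled_difficulty(delta_new[m], w[m])
    }
    delta_new - mean(delta_new)
  }
  while (it < max_iter) {
    it <- it + 1L
    delta_new <- one_step(delta)
    if (max(abs(delta_new - delta)) < tol) {
      delta <- delta_new
      converged <- TRUE
      break
    }
    # items far off their sample's range approach the fixed point in tiny
    # geometric steps (per-sweep ratio ~ r/(r+l), arbitrarily close to 1 for
    # items with a handful of losses). Every 50 sweeps, extrapolate each
    # coordinate with a stable consecutive-step ratio to its geometric limit
    # (Aitken). The fixed point is unchanged; only the approach is shortened.
    if (it %% 50 == 0) {
      d1 <- delta_new - delta
      delta_next <- one_step(delta_new)
      d2 <- delta_next - delta_new
      lam <- d2 / d1
      ok <- is.finite(lam) & lam > 0 & lam < 1 - 1e-6 & abs(d2) > tol / 10
      delta_new <- delta_next
      if (any(ok)) {
        # cap the extrapolated jump; near-unit ratios imply huge factors and
        # repeated capped jumps are safer than one uncontrolled one
        jump <- pmin(pmax(d2[ok] * lam[ok] / (1 - lam[ok]), -8), 8)
        delta_new[ok] <- delta_new[ok] + jump
        delta_new <- one_step(delta_new)
      }
    }
    delta <- delta_new
  }
  if (!converged) {
    cond <- structure(
      class = c("rasch_nonconvergence", "error", "condition"),
      list(message = paste0("pairwise estimation did not converge in ",
                            max_iter, " iterations"),
           call = sys.call(-1), last_delta = stats::setNames(delta, colnames(X)))
    )
    stop(cond)
  }
  names(delta) <- colnames(X)
  # free per-item difficulties: each item's own estimating equation solved to
  # convergence while every other item is held at the constrained solution
  # (L independent 1-d fixed points); basis for member-vs-cluster gaps
  eps_con <- exp(-delta)
  eps_free <- eps_con
  for (k in seq_len(200)) {
    upd <- r / rowSums(Nij / outer(eps_free, eps_con, "+"))
    if (max(abs(log(upd) - log(eps_free))) < tol) { eps_free <- upd; break }
    eps_free <- upd
  }
  free <- stats::setNames(-log(eps_free), colnames(X))
  list(delta = delta, converged = converged, n_iter = it,
       excluded = excluded, X = X, w = w, free_delta = free)
}
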