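#' Standardized Rasch residuals
#'
#' For every observed response, the expected score is
#' \eqn{\pi_{ni} = } [pass_probability]\eqn{(\beta_n, \delta_i)}, the response
#' variance is \eqn{W_{ni} = \pi_{ni}(1-\pi_{ni})} and the standardized
#' residual is \eqn{z_{ni} = (x_{ni} - \pi_{ni})/\sqrt{W_{ni}}}. These
#' underpin all infit/outfit statistics and the DIF test.
#'
#' @param data a [response_matrix].
#' @param key a `rasch_key` covering all items in `data`.
#' @param abilities data.frame with `person_id` and `beta` (e.g. from
#'   [score_abilities()] or a fitted model's `abilities` element).
#' @return An object of class `rasch_residuals`: list with matrices `z` and
#'   `W` (persons x items, `NA` where no record exists) plus `x` (observed
#'   scores) and the item table.
#' @export
rasch_residuals <- function(data, key, abilities) {
  stopifnot(inherits(data, "response_matrix"))
  beta <- abilities$beta[match(data$persons, abilities$person_id)]
  if (any(!is.finite(beta))) {
    stop("missing or non-finite ability for ", sum(!is.finite(beta)),
         " person(s)")
  }
  delta <- key_lookup(key, data$items$item_id)
  X <- rm_wide(data)
  P <- pass_probability(matrix(beta, data$N, data$L),
                        matrix(delta, data$N, data$L, byrow = TRUE))
  dimnames(P) <- dimnames(X)
  P[is.na(X)] <- NA
  W <- P * (1 - P)
  Z <- (X - P) / sqrt(W)
  structure(list(z = Z, W = W, x = X, items = data$items,
                 persons = data$persons),
            class = "rasch_residuals")
}

#' @export
print.rasch_residuals <- function(x, ...) {
  cat("Standardized Rasch residuals:", length(x$persons), "persons x",
      nrow(x$items), "items; mean z^2 =",
      format(mean(x$z^2, na.rm = TRUE), digits = 4), "\n")
  invisible(x)
}

#' Item and person fit statistics
#'
#' Outfit is the unweighted mean of squared standardized residuals (a
#' chi-square statistic sensitive to tail misfit); infit is the
#' information-weighted mean, \eqn{\sum W z^2 / \sum W}, sensitive near the
#' center of the ability distribution. Values near 1 indicate fit; the
#' conventional cutoff for misfit is 1.5.
#'
#' @param res a [rasch_residuals] object.
#' @return data.frame with one row per item (`item_id`, `instrument`, `w`,
#'   `infit`, `outfit`) or per person (`person_id`, `n_items`, `infit`,
#'   `outfit`). Items or persons without any residual are excluded.
#' @export
item_fit <- function(res) {
  stopifnot(inherits(res, "rasch_residuals"))
  z2 <- res$z^2
  n <- colSums(!is.na(z2))
  keep <- n > 0
  out <- data.frame(
    item_id = res$items$item_id,
    instrument = res$items$instrument,
    w = n,
    infit = colSums(res$W * z2, na.rm = TRUE) / colSums(res$W, na.rm = TRUE),
    outfit = colMeans(z2, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[keep, , drop = FALSE]
}

#' @rdname item_fit
#' @export
person_fit <- function(res) {
  stopifnot(inherits(res, "rasch_residuals"))
  z2 <- res$z^2
  n <- rowSums(!is.na(z2))
  out <- data.frame(
    person_id = res$persons,
    n_items = n,
    infit = rowSums(res$W * z2, na.rm = TRUE) / rowSums(res$W, na.rm = TRUE),
    outfit = rowMeans(z2, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[n > 0, , drop = FALSE]
}

#' Equate-cluster fit statistics
#'
#' Generalized fit statistics that measure how far the individual items of an
#' equate cluster sit from the shared cluster difficulty. Equate outfit is
#' \eqn{u_q = \sum_{i \in Q_q} \sum_n z_{ni}^2 / (w_q w_i)}: the unweighted
#' mean square over all responses to member items, equivalently the mean of
#' the members' item outfits. Equate infit \eqn{\nu_q} analogously averages
#' the members' information-weighted mean squares. For a singleton cluster
#' both reduce exactly to the member's conventional item statistics. They are
#' interpreted like item infit/outfit, with the same 1.5 cutoff.
#'
#' @param res a [rasch_residuals] object (from the constrained model).
#' @param clusters an [equate_clusters] definition; statistics are computed
#'   for every cluster (active or not) with at least one member present in
#'   the residuals.
#' @return data.frame `cluster_id`, `active`, `n_members`, `infit`, `outfit`.
#' @export
equate_fit <- function(res, clusters) {
  stopifnot(inherits(res, "rasch_residuals"))
  members <- cluster_members(clusters, all = TRUE)
  if (length(members) == 0) stop("no clusters defined")
  fit <- item_fit(res)
  active <- vapply(names(members), function(q) {
    any(clusters$active[clusters$cluster_id == q])
  }, logical(1))
  rows <- lapply(names(members), function(q) {
    m <- intersect(members[[q]], fit$item_id)
    if (length(m) == 0) stop("cluster ", q, " has no members with residuals")
    idx <- match(m, fit$item_id)
    data.frame(cluster_id = q, active = active[[q]], n_members = length(m),
               infit = mean(fit$infit[idx]), outfit = mean(fit$outfit[idx]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit-based item purification
#'
#' Iteratively refits the model and removes misfitting items until every
#' remaining item has infit and outfit below the threshold. One item is
#' removed per refit -- the worst by max(infit, outfit), ties broken by item
#' id -- because each removal changes all estimates. Cluster definitions are
#' pruned alongside the items.
#'
#' @param data a [response_matrix] with at least 2 items.
#' @param clusters optional [equate_clusters] definition.
#' @param threshold mean-square cutoff; items with infit or outfit at or above
#'   it are candidates for removal. The conventional value is 1.5.
#' @param constrained passed to [rasch_fit()].
#' @param ... further arguments to [rasch_fit()].
#' @return An object of class `purify_result`: list with `fit` (final
#'   [rasch_fit]), `kept` (item ids), `removed` (data.frame `step`,
#'   `item_id`, `infit`, `outfit` in removal order), and `threshold`. If the
#'   loop would remove every item an error reports the removal history.
#' @export
purify <- function(data, clusters = NULL, threshold = 1.5,
                   constrained = TRUE, ...) {
  stopifnot(inherits(data, "response_matrix"))
  if (data$L < 2) stop("need at least 2 items")
  removed <- data.frame(step = integer(0), item_id = character(0),
                        infit = numeric(0), outfit = numeric(0),
                        stringsAsFactors = FALSE)
  cur <- data
  cl <- clusters
  step <- 0L
  repeat {
    fit <- rasch_fit(cur, cl, constrained = constrained, abilities = "wle", ...)
    res <- rasch_residuals(cur, fit$key, fit$abilities)
    ifit <- item_fit(res)
    worst_stat <- pmax(ifit$infit, ifit$outfit)
    failing <- worst_stat >= threshold
    if (!any(failing)) break
    ord <- order(-worst_stat, ifit$item_id)
    victim <- ifit[ord[1], ]
    step <- step + 1L
    removed <- rbind(removed, data.frame(
      step = step, item_id = victim$item_id, infit = victim$infit,
      outfit = victim$outfit, stringsAsFactors = FALSE))
    keep_rec <- cur$records$item_id != victim$item_id
    if (length(unique(cur$records$item_id[keep_rec])) < 2) {
      stop("purification removed all but one item; removal history: ",
           paste(removed$item_id, collapse = ", "))
    }
    cur <- response_matrix(cur$records[keep_rec, , drop = FALSE])
    if (!is.null(cl)) {
      cl2 <- cl[cl$item_id != victim$item_id, , drop = FALSE]
      cl <- if (nrow(cl2) > 0) equate_clusters(as.data.frame(cl2)) else NULL
    }
  }
  structure(list(fit = fit, kept = fit$key$item_id, removed = removed,
                 threshold = threshold),
            class = "purify_result")
}

#' @export
print.purify_result <- function(x, ...) {
  cat("Item purification (threshold ", x$threshold, "): ",
      length(x$kept), " items kept, ", nrow(x$removed), " removed\n", sep = "")
  if (nrow(x$removed) > 0) print.data.frame(x$removed, digits = 3)
  invisible(x)
}
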