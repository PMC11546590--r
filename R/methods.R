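#' @export
print.rasch_fit <- function(x, ...) {
  cat("Constrained Rasch calibration\n")
  cat("Call: "); print(x$call)
  cat(nrow(x$key), "items,", x$data$N, "persons;",
      if (x$constrained) paste0(length(x$constraint_set), " active cluster(s)")
      else "unconstrained", "\n")
  cat("Converged in", x$n_iter, "iterations\n")
  if (length(x$excluded) > 0) {
    cat("Excluded items:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Summarize a Rasch calibration
#'
#' Combines the key with item fit statistics (when abilities are available)
#' and equate-cluster fit statistics into one report.
#'
#' @param object a `rasch_fit`.
#' @param ... unused.
#' @return An object of class `summary.rasch_fit` with elements `key`,
#'   `item_fit`, `equate_fit` (when clusters are present), `abilities`
#'   (five-number summary) and convergence information.
#' @export
summary.rasch_fit <- function(object, ...) {
  ifit <- efit <- ab_sum <- NULL
  if (!is.null(object$abilities)) {
    res <- rasch_residuals(object$data, object$key, object$abilities)
    ifit <- item_fit(res)
    if (!is.null(object$clusters)) efit <- equate_fit(res, object$clusters)
    ab_sum <- summary(object$abilities$beta)
  }
  structure(list(key = object$key, item_fit = ifit, equate_fit = efit,
                 abilities = ab_sum, converged = object$converged,
                 n_iter = object$n_iter, excluded = object$excluded,
                 constraint_set = object$constraint_set),
            class = "summary.rasch_fit")
}

#' @export
print.summary.rasch_fit <- function(x, ...) {
  print(x$key)
  if (!is.null(x$item_fit)) {
    cat("\nItem fit (infit/outfit, cutoff 1.5):\n")
    print.data.frame(utils::head(x$item_fit, 10), digits = 3)
    nbad <- sum(pmax(x$item_fit$infit, x$item_fit$outfit) >= 1.5)
    cat(nbad, "item(s) at or above the 1.5 cutoff\n")
  }
  if (!is.null(x$equate_fit)) {
    cat("\nEquate-cluster fit:\n")
    print.data.frame(x$equate_fit, digits = 3)
  }
  if (!is.null(x$abilities)) {
    cat("\nAbilities (logits):\n")
    print(x$abilities)
  }
  invisible(x)
}

#' @export
coef.rasch_fit <- function(object, ...) {
  stats::setNames(object$key$difficulty, object$key$item_id)
}

#' Predicted pass probabilities
#'
#' @param object a `rasch_fit` with abilities.
#' @param newdata optional [response_matrix]; defaults to the fitted data.
#'   Items must exist in the key; persons must exist in the fit's abilities.
#' @param ... unused.
#' @return data.frame `person_id`, `item_id`, `pi` for every observed record.
#' @export
predict.rasch_fit <- function(object, newdata = NULL, ...) {
  if (is.null(object$abilities)) {
    stop("fit has no abilities; refit with abilities = \"wle\"")
  }
  data <- if (is.null(newdata)) object$data else newdata
  stopifnot(inherits(data, "response_matrix"))
  rec <- data$records
  beta <- object$abilities$beta[match(rec$person_id,
                                      object$abilities$person_id)]
  if (any(!is.finite(beta))) stop("person(s) missing from fitted abilities")
  delta <- key_lookup(object$key, rec$item_id)
  data.frame(person_id = rec$person_id, item_id = rec$item_id,
             pi = pass_probability(beta, delta), stringsAsFactors = FALSE)
}

#' @export
residuals.rasch_fit <- function(object, ...) {
  if (is.null(object$abilities)) {
    stop("fit has no abilities; refit with abilities = \"wle\"")
  }
  rasch_residuals(object$data, object$key, object$abilities)
}

#' Simulate responses from a fitted calibration
#'
#' Draws Bernoulli responses for the observed (person, item) pattern of the
#' fitted data, from the fitted difficulties and abilities.
#'
#' @param object a `rasch_fit` with abilities.
#' @param nsim number of simulated datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of [response_matrix] objects of length `nsim`.
#' @export
simulate.rasch_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$abilities)) {
    stop("fit has no abilities; refit with abilities = \"wle\"")
  }
  if (!is.null(seed)) set.seed(seed)
  pr <- predict(object)
  rec <- object$data$records
  lapply(seq_len(nsim), function(s) {
    rec$score <- as.integer(stats::runif(nrow(rec)) < pr$pi)
    response_matrix(rec)
  })
}

#' Plot a Rasch calibration
#'
#' `type = "icc"` draws theoretical item characteristic curves (optionally a
#' subset of items); `type = "map"` draws an item map of difficulties by
#' instrument, with equate-cluster difficulties marked.
#'
#' @param x a `rasch_fit`.
#' @param type `"icc"` or `"map"`.
#' @param items optional character vector of item ids for `type = "icc"`.
#' @param ... passed to the underlying plot call.
#' @export
plot.rasch_fit <- function(x, type = c("icc", "map"), items = NULL, ...) {
  type <- match.arg(type)
  key <- x$key
  if (type == "icc") {
    if (is.null(items)) items <- utils::head(key$item_id, 8)
    delta <- key_lookup(key, items)
    beta_grid <- seq(min(delta) - 4, max(delta) + 4, length.out = 200)
    cols <- grDevices::hcl.colors(length(items), "Dark 2")
    graphics::plot(range(beta_grid), c(0, 1), type = "n",
                   xlab = "Ability (logits)", ylab = "P(pass)", ...)
    for (i in seq_along(items)) {
      graphics::lines(beta_grid, pass_probability(beta_grid, delta[i]),
                      col = cols[i])
    }
    graphics::legend("topleft", legend = items, col = cols, lty = 1,
                     cex = 0.7, bty = "n")
  } else {
    instr <- factor(key$instrument)
    graphics::stripchart(key$difficulty ~ instr, vertical = FALSE,
                         method = "jitter", pch = 16,
                         xlab = "Difficulty (logits)", ...)
    in_cluster <- !is.na(key$cluster_id)
    if (any(in_cluster)) {
      graphics::points(key$difficulty[in_cluster],
                       as.integer(instr)[in_cluster], pch = 1, cex = 2)
    }
  }
  invisible(x)
}
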