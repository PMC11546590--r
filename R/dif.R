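#' Differential item functioning test within an equate cluster
#'
#' Tests whether the items of an equate cluster behave differently at equal
#' ability, by an analysis of variance on the standardized residuals of the
#' constrained model: \eqn{z_{ni} = \beta_n + G_i + \beta_n G_i + \epsilon_{ni}}
#' with ability as a continuous covariate, item as a factor, and their
#' interaction, using sequential sums of squares (ability first). A
#' significant F test indicates DIF; both the item main effect and the
#' interaction are reported. The effect size \eqn{\eta^2} is the proportion of
#' total variance attributed to the item effect, classified as none
#' (< 0.01), small (< 0.06), medium (< 0.14) or large (>= 0.14).
#'
#' The report also includes the largest absolute gap between a member's
#' *free* difficulty (a single unconstrained update from the converged
#' constrained solution) and the shared cluster difficulty; gaps below 0.2
#' logits are the working range in which keeping the cluster active is known
#' to beat deactivating it. The decision to deactivate remains with the
#' analyst.
#'
#' @param res a [rasch_residuals] object from the constrained model, or a
#'   `rasch_fit` (its residuals are computed on the fly, requiring abilities).
#' @param clusters an [equate_clusters] definition; clusters with fewer than
#'   2 members present are skipped (or an error when `cluster_id` names one
#'   explicitly).
#' @param cluster_id optional single cluster to test.
#' @param abilities data.frame `person_id`, `beta`; taken from the fit when
#'   `res` is a `rasch_fit`.
#' @param alpha significance level for flagging (default 0.05).
#' @param free_difficulties optional named vector of free member difficulties
#'   (taken from the fit's `free_delta` when `res` is a `rasch_fit`), used
#'   for the member-vs-cluster difficulty gap.
#' @param key optional constrained `rasch_key` supplying the cluster
#'   difficulty the gaps are measured from (taken from the fit when `res`
#'   is a `rasch_fit`; otherwise gaps fall back to deviations from the
#'   members' mean free difficulty).
#' @return An object of class `dif_result`: data.frame with one row per
#'   tested cluster: `cluster_id`, `n_members`, `F_item`, `p_item`,
#'   `F_interaction`, `p_interaction`, `eta_squared`, `severity`,
#'   `significant`, `max_gap` (`NA` without `free_difficulties`) and
#'   `unreliable` (`TRUE` when member ability ranges do not overlap).
#' @export
dif_test <- function(res, clusters = NULL, cluster_id = NULL,
                     abilities = NULL, alpha = 0.05,
                     free_difficulties = NULL, key = NULL) {
  if (inherits(res, "rasch_fit")) {
    fit <- res
    if (is.null(clusters)) clusters <- fit$clusters
    if (is.null(abilities)) abilities <- fit$abilities
    if (is.null(free_difficulties)) free_difficulties <- fit$free_delta
    if (is.null(key)) key <- fit$key
    if (is.null(abilities)) {
      stop("fit has no abilities; refit with abilities = \"wle\" or supply them")
    }
    res <- rasch_residuals(fit$data, fit$key, abilities)
  }
  stopifnot(inherits(res, "rasch_residuals"))
  if (is.null(clusters)) stop("no cluster definition supplied")
  if (is.null(abilities)) stop("abilities required for the DIF model")
  members <- cluster_members(clusters, all = TRUE)
  if (!is.null(cluster_id)) {
    if (!cluster_id %in% names(members)) stop("unknown cluster: ", cluster_id)
    members <- members[cluster_id]
    if (length(intersect(members[[1]], res$items$item_id)) < 2) {
      stop("cluster ", cluster_id, " has fewer than 2 members with data")
    }
  }
  beta <- abilities$beta[match(res$persons, abilities$person_id)]
  rows <- lapply(names(members), function(q) {
    m <- intersect(members[[q]], res$items$item_id)
    if (length(m) < 2) return(NULL)
    idx <- match(m, res$items$item_id)
    long <- do.call(rbind, lapply(idx, function(j) {
      obs <- which(!is.na(res$z[, j]))
      data.frame(z = res$z[obs, j], beta = beta[obs],
                 item = res$items$item_id[j], stringsAsFactors = FALSE)
    }))
    long$item <- factor(long$item)
    fit_lm <- stats::lm(z ~ beta * item, data = long)
    av <- stats::anova(fit_lm)
    ss <- av[["Sum Sq"]]
    names(ss) <- rownames(av)
    eta2 <- ss[["item"]] / sum(ss)
    rng <- tapply(long$beta, long$item, range)
    lo <- max(vapply(rng, `[`, numeric(1), 1))
    hi <- min(vapply(rng, `[`, numeric(1), 2))
    gap <- NA_real_
    if (!is.null(free_difficulties) && all(m %in% names(free_difficulties))) {
      centre <- if (!is.null(key) && all(m %in% key$item_id)) {
        mean(key$difficulty[match(m, key$item_id)])
      } else {
        mean(free_difficulties[m], na.rm = TRUE)
      }
      gap <- max(abs(free_difficulties[m] - centre), na.rm = TRUE)
    }
    data.frame(
      cluster_id = q, n_members = length(m),
      F_item = av["item", "F value"], p_item = av["item", "Pr(>F)"],
      F_interaction = av["beta:item", "F value"],
      p_interaction = av["beta:item", "Pr(>F)"],
      eta_squared = eta2,
      severity = dif_severity(eta2),
      significant = av["item", "Pr(>F)"] < alpha,
      max_gap = gap,
      unreliable = lo >= hi,
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop("no cluster with >= 2 members to test")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "ss_type") <- "sequential (ability, item, ability:item)"
  class(out) <- c("dif_result", "data.frame")
  out
}

dif_severity <- function(eta2) {
  cut_labels <- c("none", "small", "medium", "large")
  cut_labels[findInterval(eta2, c(0.01, 0.06, 0.14)) + 1]
}

#' @export
print.dif_result <- function(x, ...) {
  cat("DIF test (ANOVA on standardized residuals, alpha = ",
      attr(x, "alpha"), ")\n", sep = "")
  print.data.frame(x, digits = 3)
  invisible(x)
}
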