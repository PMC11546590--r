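#' Define one cell of the simulation design
#'
#' A simulation condition describes how multi-instrument item response data
#' are generated: number of instruments, item difficulty ranges, number and
#' placement of equate clusters, misspecification of the equate items, and
#' the ability distributions of the instrument samples.
#'
#' Difficulty ranges per overlap level (two instruments):
#' `no_overlap` = \[-5,-3\] and \[3,5\]; `close` = \[-3,-0.1\] and
#' \[0.1,3\]; `overlap` = \[-2,1\] and \[-1,2\]. With three instruments the
#' middle instrument receives a range of the same width centered midway
#' between the two listed ranges. `ranges` overrides the preset (e.g. two
#' identical ranges give strictly parallel instruments).
#'
#' Placement of the equate-cluster difficulties along the scale:
#' `center` = within the middle quarter of the union of ranges;
#' `one_instrument` = within instrument 1's range only; `spread` = across
#' the union of all ranges; `extreme` = within the lowest 15% of instrument
#' 1's range. "Evenly spaced" positions are the interior points of an
#' equally spaced grid (a single cluster sits at the interval midpoint).
#'
#' @param n_instruments 2 or 3.
#' @param overlap one of `"no_overlap"`, `"close"`, `"overlap"`.
#' @param n_equates number of equate clusters (1, 2 or 5 in the factorial
#'   design; any positive count is accepted).
#' @param placement one of `"center"`, `"one_instrument"`, `"spread"`,
#'   `"extreme"`.
#' @param delta_shift misspecification in logits, added to the equate-item
#'   difficulty of every instrument after the first (0 = correctly specified;
#'   the factorial design sweeps 0 to 2 by 0.1).
#' @param abilities `"equal"`: all samples N(0,1); `"different"`: N(-1,1) and
#'   N(1,1) for two instruments, N(-1.5,1), N(0.5,1), N(2.5,1) for three.
#' @param n_persons persons per instrument (design default 1000).
#' @param n_items unique (non-equate) items per instrument (design default 10).
#' @param ranges optional list of length `n_instruments` of numeric ranges
#'   overriding the overlap preset.
#' @return An object of class `sim_condition`.
#' @export
sim_condition <- function(n_instruments = 2,
                          overlap = c("close", "no_overlap", "overlap"),
                          n_equates = 5,
                          placement = c("spread", "center", "one_instrument",
                                        "extreme"),
                          delta_shift = 0,
                          abilities = c("equal", "different"),
                          n_persons = 1000, n_items = 10, ranges = NULL) {
  overlap <- match.arg(overlap)
  placement <- match.arg(placement)
  abilities <- match.arg(abilities)
  stopifnot(n_instruments %in% c(2, 3), n_equates >= 1,
            delta_shift >= 0, n_persons >= 1, n_items >= 2)
  if (is.null(ranges)) {
    ranges <- overlap_ranges(overlap, n_instruments)
  } else {
    stopifnot(length(ranges) == n_instruments)
    ranges <- lapply(ranges, function(r) sort(as.numeric(r[1:2])))
  }
  mu <- ability_means(abilities, n_instruments)
  structure(
    list(n_instruments = n_instruments, overlap = overlap,
         n_equates = n_equates, placement = placement,
         delta_shift = delta_shift, abilities = abilities,
         ability_means = mu, n_persons = n_persons, n_items = n_items,
         ranges = ranges),
    class = "sim_condition"
  )
}

overlap_ranges <- function(overlap, n_instruments) {
  two <- switch(overlap,
    no_overlap = list(c(-5, -3), c(3, 5)),
    close = list(c(-3, -0.1), c(0.1, 3)),
    overlap = list(c(-2, 1), c(-1, 2))
  )
  if (n_instruments == 2) return(two)
  width <- diff(two[[1]])
  mid <- mean(c(mean(two[[1]]), mean(two[[2]])))
  list(two[[1]], mid + c(-width, width) / 2, two[[2]])
}

ability_means <- function(abilities, n_instruments) {
  if (abilities == "equal") return(rep(0, n_instruments))
  if (n_instruments == 2) c(-1, 1) else c(-1.5, 0.5, 2.5)
}

#' @export
print.sim_condition <- function(x, ...) {
  cat("Simulation condition:", x$n_instruments, "instruments,",
      x$overlap, "ranges,", x$n_equates, "equate cluster(s) (",
      x$placement, "), shift", x$delta_shift, "logits,",
      x$abilities, "abilities,", x$n_persons, "persons/instrument\n")
  invisible(x)
}

equate_positions <- function(k, ranges, placement) {
  un <- range(unlist(ranges))
  interval <- switch(placement,
    center = mean(un) + c(-1, 1) * diff(un) / 8,
    one_instrument = ranges[[1]],
    spread = un,
    extreme = c(ranges[[1]][1], ranges[[1]][1] + 0.15 * diff(ranges[[1]]))
  )
  seq(interval[1], interval[2], length.out = k + 2)[seq_len(k) + 1]
}

#' Generate complete multi-instrument Rasch data for a condition
#'
#' Draws unique-item difficulties uniformly within each instrument's range,
#' places equate-cluster items per the placement rule (each cluster has one
#' copy per instrument; copies in instruments 2 and 3 are offset by the
#' misspecification `delta_shift`), draws abilities per the condition, and
#' generates Bernoulli responses of *every* person to *every* item. The
#' complete data are the reference situation; [to_incomplete_design()] with
#' the returned assignment produces the realistic split where each person
#' only answers their own instrument.
#'
#' @param cond a [sim_condition].
#' @param seed integer seed; identical seeds give identical data.
#' @return list with `data` (complete [response_matrix]), `truth`
#'   (data.frame `item_id`, `instrument`, `delta_true`), `clusters` (active
#'   [equate_clusters] linking the copies), and `assignment` (person ->
#'   instrument).
#' @export
sim_generate <- function(cond, seed = 1L) {
  stopifnot(inherits(cond, "sim_condition"))
  set.seed(seed)
  K <- cond$n_instruments
  base_eq <- equate_positions(cond$n_equates, cond$ranges, cond$placement)
  item_id <- character(0); instrument <- character(0); delta <- numeric(0)
  cl_id <- character(0); cl_item <- character(0)
  for (k in seq_len(K)) {
    instr_k <- paste0("instr", k)
    uid <- sprintf("%s_item%02d", instr_k, seq_len(cond$n_items))
    udelta <- stats::runif(cond$n_items, cond$ranges[[k]][1], cond$ranges[[k]][2])
    eid <- sprintf("eq%02d_%s", seq_len(cond$n_equates), instr_k)
    edelta <- base_eq + if (k >= 2) cond$delta_shift else 0
    item_id <- c(item_id, uid, eid)
    instrument <- c(instrument, rep(instr_k, cond$n_items + cond$n_equates))
    delta <- c(delta, udelta, edelta)
    cl_id <- c(cl_id, sprintf("eq%02d", seq_len(cond$n_equates)))
    cl_item <- c(cl_item, eid)
  }
  n_total <- K * cond$n_persons
  beta <- stats::rnorm(n_total,
                       rep(cond$ability_means, each = cond$n_persons), 1)
  persons <- sprintf("p%04d", seq_len(n_total))
  P <- pass_probability(matrix(beta, n_total, length(delta)),
                        matrix(delta, n_total, length(delta), byrow = TRUE))
  X <- matrix(as.integer(stats::runif(length(P)) < P), n_total,
              dimnames = list(persons, item_id))
  names(instrument) <- item_id
  data <- rm_from_wide(X, instrument)
  truth <- data.frame(item_id = item_id, instrument = instrument,
                      delta_true = delta, stringsAsFactors = FALSE)
  truth <- truth[order(truth$item_id), , drop = FALSE]
  rownames(truth) <- NULL
  clusters <- equate_clusters(data.frame(
    cluster_id = cl_id, item_id = cl_item, active = TRUE,
    stringsAsFactors = FALSE))
  assignment <- stats::setNames(
    rep(paste0("instr", seq_len(K)), each = cond$n_persons), persons)
  list(data = data, truth = truth, clusters = clusters,
       assignment = assignment, beta = stats::setNames(beta, persons))
}

#' Reference difficulties from complete data
#'
#' Fits the unconstrained Rasch model to the complete (every person x every
#' item) data. These estimates serve as the reference "true" difficulties
#' against which the split-design calibrations are evaluated.
#'
#' @param gen output of [sim_generate()] or a complete [response_matrix].
#' @param ... passed to [rasch_fit()].
#' @return a `rasch_key`.
#' @export
reference_truth <- function(gen, ...) {
  data <- if (inherits(gen, "response_matrix")) gen else gen$data
  rasch_fit(data, clusters = NULL, constrained = FALSE,
            abilities = "none", ...)$key
}

#' Alignment of estimated against true difficulties
#'
#' Measures how well a calibration reproduces the common scale by the
#' regression \eqn{\delta = c + b\hat\delta + \gamma k} of true on estimated
#' difficulties with a numeric instrument index \eqn{k} (0, 1, ...). The
#' misalignment \eqn{\gamma} is the single index coefficient: the average
#' vertical offset between successive instruments' regression lines; 0 means
#' all instruments' estimates lie on one line. With two instruments this is
#' exactly the indicator-dummy coefficient. `rho` is the plain correlation of
#' true with estimated difficulties pooled over instruments. Lower
#' \eqn{|\gamma|} and higher `rho` are better. Per-instrument dummy offsets
#' are returned as a diagnostic.
#'
#' @param true numeric vector of true (reference) difficulties.
#' @param estimated numeric vector of estimated difficulties, same items.
#' @param instrument character vector of instrument labels, same length;
#'   at least 2 items per instrument are required.
#' @return An object of class `alignment_metrics`: list with `rho`, `gamma`,
#'   `b`, `c`, `gamma_by_instrument`, `n_items`.
#' @export
misalignment <- function(true, estimated, instrument) {
  stopifnot(length(true) == length(estimated),
            length(true) == length(instrument))
  ok <- is.finite(true) & is.finite(estimated)
  true <- true[ok]; estimated <- estimated[ok]
  instrument <- factor(instrument[ok])
  if (any(table(instrument) < 2) || nlevels(instrument) < 2) {
    stop("need >= 2 instruments with >= 2 items each")
  }
  k <- as.integer(instrument) - 1L
  fit <- stats::lm(true ~ estimated + k)
  co <- stats::coef(fit)
  if (anyNA(co)) stop("rank-deficient alignment design")
  dummies <- stats::coef(stats::lm(true ~ estimated + instrument))[-(1:2)]
  names(dummies) <- levels(instrument)[-1]
  structure(
    list(rho = stats::cor(true, estimated),
         gamma = unname(co[["k"]]),
         b = unname(co[["estimated"]]), c = unname(co[["(Intercept)"]]),
         gamma_by_instrument = dummies, n_items = length(true)),
    class = "alignment_metrics"
  )
}

#' @export
print.alignment_metrics <- function(x, ...) {
  cat(sprintf("Alignment: rho = %.4f, gamma = %+.4f (b = %.3f, c = %+.3f, %d items)\n",
              x$rho, x$gamma, x$b, x$c, x$n_items))
  invisible(x)
}

#' Run one simulation cell
#'
#' Per replicate: generate complete data, obtain reference difficulties from
#' the complete data, split to the incomplete design, fit the constrained
#' model (active equate clusters) and the unconstrained model (no
#' constraints), and evaluate both against the reference via
#' [misalignment()].
#'
#' @param cond a [sim_condition].
#' @param replicates number of replicates.
#' @param seed integer; replicate seeds are drawn reproducibly from it.
#' @return An object of class `sim_cell`: list with `replicates` (data.frame
#'   of per-replicate `model`, `rho`, `gamma`, `b`, `c`), `summary`
#'   (data.frame of means by model), `cond`, and `n_failed` (failed
#'   replicates are logged and excluded).
#' @export
run_cell <- function(cond, replicates = 10, seed = 1L) {
  stopifnot(inherits(cond, "sim_condition"))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, replicates)
  rows <- list()
  n_failed <- 0L
  for (r in seq_len(replicates)) {
    res <- tryCatch(run_replicate(cond, rep_seeds[r]), error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      message("replicate ", r, " failed: ", conditionMessage(res))
      next
    }
    res$replicate <- r
    rows[[length(rows) + 1L]] <- res
  }
  if (length(rows) == 0) stop("all replicates failed")
  reps <- do.call(rbind, rows)
  agg <- stats::aggregate(reps[c("rho", "gamma", "abs_gamma")],
                          by = list(model = reps$model), FUN = mean)
  structure(list(replicates = reps, summary = agg, cond = cond,
                 n_failed = n_failed),
            class = "sim_cell")
}

run_replicate <- function(cond, seed) {
  gen <- sim_generate(cond, seed)
  ref <- reference_truth(gen)
  split <- suppressWarnings(to_incomplete_design(gen$data, gen$assignment))
  fit_c <- suppressWarnings(
    rasch_fit(split, gen$clusters, constrained = TRUE, abilities = "none"))
  fit_u <- suppressWarnings(
    rasch_fit(split, gen$clusters, constrained = FALSE, abilities = "none"))
  row1 <- align_row(ref, fit_c$key, "constrained")
  row2 <- align_row(ref, fit_u$key, "unconstrained")
  rbind(row1, row2)
}

align_row <- function(ref, key, model, items = ref$item_id) {
  common <- intersect(intersect(ref$item_id, key$item_id), items)
  i1 <- match(common, ref$item_id)
  i2 <- match(common, key$item_id)
  m <- misalignment(ref$difficulty[i1], key$difficulty[i2], ref$instrument[i1])
  data.frame(model = model, rho = m$rho, gamma = m$gamma,
             abs_gamma = abs(m$gamma), b = m$b, c = m$c,
             stringsAsFactors = FALSE)
}

#' @export
print.sim_cell <- function(x, ...) {
  print(x$cond)
  print.data.frame(x$summary, digits = 4)
  if (x$n_failed > 0) cat(x$n_failed, "replicate(s) failed and were excluded\n")
  invisible(x)
}

#' Run a factorial simulation design
#'
#' Evaluates every cell of a condition grid and summarises alignment by
#' overlap level and ability setting (marginal means over the other factors),
#' the headline comparison of the simulation study.
#'
#' @param grid data.frame with columns `n_instruments`, `overlap`,
#'   `n_equates`, `placement`, `abilities` and optionally `delta_shift`;
#'   defaults to the full correctly-specified factorial (2 and 3 instruments
#'   x 3 overlap levels x 1/2/5 clusters x 4 placements x 2 ability
#'   settings, shift 0).
#' @param replicates replicates per cell.
#' @param seed integer seed.
#' @param n_persons,n_items forwarded to [sim_condition()].
#' @return An object of class `sim_design`: list with `cells` (per-cell,
#'   per-model means), `marginal` (means by overlap x abilities x model) and
#'   `replicates` used.
#' @export
run_design <- function(grid = NULL, replicates = 10, seed = 1L,
                       n_persons = 1000, n_items = 10) {
  if (is.null(grid)) grid <- design_grid()
  if (is.null(grid$delta_shift)) grid$delta_shift <- 0
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  cells <- list()
  for (i in seq_len(nrow(grid))) {
    cond <- sim_condition(
      n_instruments = grid$n_instruments[i],
      overlap = as.character(grid$overlap[i]),
      n_equates = grid$n_equates[i],
      placement = as.character(grid$placement[i]),
      delta_shift = grid$delta_shift[i],
      abilities = as.character(grid$abilities[i]),
      n_persons = n_persons, n_items = n_items
    )
    cell <- run_cell(cond, replicates = replicates, seed = cell_seeds[i])
    s <- cell$summary
    s <- cbind(grid[rep(i, nrow(s)), , drop = FALSE], s, row.names = NULL)
    cells[[i]] <- s
  }
  cells <- do.call(rbind, cells)
  marginal <- stats::aggregate(
    cells[c("rho", "gamma", "abs_gamma")],
    by = list(overlap = cells$overlap, abilities = cells$abilities,
              model = cells$model),
    FUN = mean)
  structure(list(cells = cells, marginal = marginal, replicates = replicates),
            class = "sim_design")
}

#' @rdname run_design
#' @export
design_grid <- function() {
  expand.grid(
    n_instruments = c(2, 3),
    overlap = c("no_overlap", "close", "overlap"),
    n_equates = c(1, 2, 5),
    placement = c("center", "one_instrument", "spread", "extreme"),
    abilities = c("equal", "different"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.sim_design <- function(x, ...) {
  cat("Simulation design:", nrow(x$cells) / 2, "cells,",
      x$replicates, "replicates each\n")
  cat("Marginal means by overlap x abilities:\n")
  print.data.frame(x$marginal, digits = 4)
  invisible(x)
}

#' Misspecification breakpoint
#'
#' Sweeps the equate-cluster misspecification from 0 to 2 logits and finds
#' the smallest amount at which the unconstrained model outperforms the
#' constrained model, i.e. where forcing a wrong anchor hurts more than
#' having no anchor. The comparison metric is mean |gamma| (misalignment),
#' with mean rho as tiebreaker.
#'
#' @param cond a [sim_condition]; its `delta_shift` is replaced by the sweep.
#' @param deltas misspecification grid in logits.
#' @param replicates replicates per grid step.
#' @param seed integer seed.
#' @return An object of class `sim_breakpoint`: list with `breakpoint` (the
#'   smallest sweep value where the unconstrained model wins, or `Inf` when
#'   there is no crossover in range, reported as "> max"), `sweep`
#'   (data.frame per step and model) and `cond`.
#' @export
misfit_breakpoint <- function(cond, deltas = seq(0, 2, by = 0.1),
                              replicates = 10, seed = 1L) {
  stopifnot(inherits(cond, "sim_condition"))
  set.seed(seed)
  step_seeds <- sample.int(.Machine$integer.max - 1L, length(deltas))
  sweep <- list()
  for (i in seq_along(deltas)) {
    cond_i <- cond
    cond_i$delta_shift <- deltas[i]
    cell <- run_cell(cond_i, replicates = replicates, seed = step_seeds[i])
    s <- cell$summary
    s$delta_shift <- deltas[i]
    sweep[[i]] <- s
  }
  sweep <- do.call(rbind, sweep)
  bp <- Inf
  for (d in sort(unique(sweep$delta_shift))) {
    con <- sweep[sweep$delta_shift == d & sweep$model == "constrained", ]
    unc <- sweep[sweep$delta_shift == d & sweep$model == "unconstrained", ]
    wins <- unc$abs_gamma < con$abs_gamma ||
      (unc$abs_gamma == con$abs_gamma && unc$rho > con$rho)
    if (wins) { bp <- d; break }
  }
  structure(list(breakpoint = bp, sweep = sweep, cond = cond,
                 max_delta = max(deltas)),
            class = "sim_breakpoint")
}

#' @export
print.sim_breakpoint <- function(x, ...) {
  lab <- if (is.infinite(x$breakpoint)) paste0("> ", format(x$max_delta))
         else format(x$breakpoint)
  cat("Misspecification breakpoint:", lab, "logits\n")
  invisible(x)
}

#' Headline breakpoint condition families
#'
#' The three condition families for which the breakpoint analysis is
#' reported: `parallel` (strictly parallel instruments sharing one working
#' range: the largely overlapping \[-2,1\]/\[-1,2\] ranges, equal
#' abilities), `different_range` (instruments sensitive to different parts of
#' the scale: close but disjoint ranges, equal abilities), and
#' `different_abilities` (close ranges, ability means -1 and +1).
#'
#' @param n_persons persons per instrument.
#' @return named list of [sim_condition] objects.
#' @export
breakpoint_families <- function(n_persons = 1000) {
  list(
    parallel = sim_condition(2, overlap = "overlap", n_equates = 2,
                             placement = "spread", abilities = "equal",
                             n_persons = n_persons),
    different_range = sim_condition(2, overlap = "close", n_equates = 2,
                                    placement = "spread", abilities = "equal",
                                    n_persons = n_persons),
    different_abilities = sim_condition(2, overlap = "close", n_equates = 2,
                                        placement = "spread",
                                        abilities = "different",
                                        n_persons = n_persons)
  )
}
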