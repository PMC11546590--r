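#' Construct a response matrix from long-format records
#'
#' A `response_matrix` holds sparse dichotomous item responses from one or
#' more instruments in long format. A missing response is represented by the
#' absence of a record, not by a sentinel code, so instruments with disjoint
#' respondent samples can live in one object. Each item belongs to exactly one
#' instrument; the instrument is an attribute of the item, not of the record.
#'
#' @param records data.frame with columns `person_id`, `item_id`, `score`
#'   (strictly 0/1) and `instrument`. At most one record per (person, item)
#'   pair; every person and every item must have at least one record (which
#'   holds by construction for long data).
#' @param w_floor items with fewer observed responses than this are flagged in
#'   the returned object (attribute `"low_w"`), never silently dropped.
#' @return An object of class `response_matrix`: a list with `records`
#'   (normalized data.frame), `items` (one row per item: `item_id`,
#'   `instrument`, `w` = number of observed responses), `persons`, and counts
#'   `N` (persons) and `L` (items).
#' @examples
#' rec <- data.frame(person_id = c("p1", "p1", "p2"),
#'                   item_id = c("a", "b", "a"),
#'                   score = c(1, 0, 0), instrument = "A")
#' rm <- response_matrix(rec)
#' rm$L
#' @export
response_matrix <- function(records, w_floor = 10) {
  stopifnot(is.data.frame(records))
  need <- c("person_id", "item_id", "score", "instrument")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop("records is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(records) == 0) stop("records is empty")
  rec <- data.frame(
    person_id = as.character(records$person_id),
    item_id = as.character(records$item_id),
    score = records$score,
    instrument = as.character(records$instrument),
    stringsAsFactors = FALSE
  )
  if (!all(rec$score %in% c(0, 1))) {
    bad <- which(!(rec$score %in% c(0, 1)))
    stop("non-binary score in row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  rec$score <- as.integer(rec$score)
  dup <- duplicated(rec[c("person_id", "item_id")])
  if (any(dup)) {
    stop("duplicate (person, item) record(s), e.g. row ",
         which(dup)[1], " (", rec$person_id[which(dup)[1]], ", ",
         rec$item_id[which(dup)[1]], ")")
  }
  # instrument must be constant within item
  instr <- tapply(rec$instrument, rec$item_id, function(x) length(unique(x)))
  if (any(instr > 1)) {
    stop("item(s) assigned to more than one instrument: ",
         paste(names(instr)[instr > 1], collapse = ", "))
  }
  items <- unique(rec[c("item_id", "instrument")])
  items <- items[order(items$item_id), , drop = FALSE]
  w <- table(rec$item_id)
  items$w <- as.integer(w[items$item_id])
  rownames(items) <- NULL
  persons <- sort(unique(rec$person_id))
  out <- structure(
    list(records = rec, items = items, persons = persons,
         N = length(persons), L = nrow(items)),
    class = "response_matrix"
  )
  attr(out, "low_w") <- items$item_id[items$w < w_floor]
  out
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("Response matrix:", x$N, "persons x", x$L, "items,",
      nrow(x$records), "responses\n")
  tab <- table(x$items$instrument)
  cat("Instruments:",
      paste(sprintf("%s (%d items)", names(tab), tab), collapse = ", "), "\n")
  low <- attr(x, "low_w")
  if (length(low) > 0) {
    cat("Flagged: ", length(low), " item(s) with few responses\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.response_matrix <- function(x, ...) x$records

# wide N x L matrix of 0/1/NA, persons in rows
rm_wide <- function(data) {
  pi_ <- match(data$records$person_id, data$persons)
  ii <- match(data$records$item_id, data$items$item_id)
  X <- matrix(NA_integer_, data$N, data$L,
              dimnames = list(data$persons, data$items$item_id))
  X[cbind(pi_, ii)] <- data$records$score
  X
}

# inverse of rm_wide: build a response_matrix from a wide matrix
rm_from_wide <- function(X, instrument) {
  obs <- which(!is.na(X), arr.ind = TRUE)
  rec <- data.frame(
    person_id = rownames(X)[obs[, 1]],
    item_id = colnames(X)[obs[, 2]],
    score = X[obs],
    instrument = instrument[obs[, 2]],
    stringsAsFactors = FALSE
  )
  response_matrix(rec)
}

#' Define equate clusters
#'
#' An equate cluster is a group of items, usually from different instruments,
#' judged to measure the same behaviour. An *active* cluster constrains its
#' members to a single pooled difficulty during calibration, so it acts as an
#' anchor bridging instruments; an inactive cluster carries no constraint.
#'
#' @param df data.frame with columns `cluster_id`, `item_id` and `active`
#'   (logical, or the strings "true"/"false"). No item may belong to two
#'   clusters.
#' @return An object of class `equate_clusters` (a normalized data.frame).
#' @export
equate_clusters <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("cluster_id", "item_id", "active")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("cluster definition is missing column(s): ", paste(miss, collapse = ", "))
  }
  out <- data.frame(
    cluster_id = as.character(df$cluster_id),
    item_id = as.character(df$item_id),
    active = parse_logical(df$active),
    stringsAsFactors = FALSE
  )
  dup <- duplicated(out$item_id)
  if (any(dup)) {
    stop("item(s) in more than one cluster row: ",
         paste(unique(out$item_id[dup]), collapse = ", "))
  }
  class(out) <- c("equate_clusters", "data.frame")
  out
}

parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  lx <- tolower(as.character(x))
  ok <- lx %in% c("true", "false")
  if (!all(ok)) stop("invalid active flag value(s): ",
                     paste(unique(x[!ok]), collapse = ", "))
  lx == "true"
}

# list cluster_id -> member item ids, active clusters only unless all = TRUE
cluster_members <- function(clusters, all = FALSE) {
  if (is.null(clusters) || nrow(clusters) == 0) return(list())
  cl <- if (all) clusters else clusters[clusters$active, , drop = FALSE]
  split(cl$item_id, cl$cluster_id)
}

check_clusters_against_data <- function(data, clusters) {
  orphans <- setdiff(clusters$item_id, data$items$item_id)
  if (length(orphans) > 0) {
    stop("cluster file references unknown item(s): ",
         paste(orphans, collapse = ", "))
  }
  invisible(TRUE)
}

#' Check that instruments form a single linked design
#'
#' Two instruments are linked when an active equate cluster contains items
#' from both (or when they share an item id). Calibrating a design whose
#' instruments fall into more than one linked component puts the components on
#' arbitrarily shifted scales, so constrained calibration requires a single
#' component.
#'
#' @param data a [response_matrix].
#' @param clusters an [equate_clusters] definition, or `NULL` for none.
#' @return An object of class `connectivity_report`: list with `components`
#'   (list of character vectors of instrument labels), `n_components`, and
#'   `linked` (`TRUE` when there is exactly one component).
#' @export
validate_connectivity <- function(data, clusters = NULL) {
  stopifnot(inherits(data, "response_matrix"))
  if (nrow(data$records) == 0) stop("empty response data")
  instruments <- sort(unique(data$items$instrument))
  comp <- seq_along(instruments)
  merge_comp <- function(labels) {
    idx <- match(labels, instruments)
    tgt <- min(comp[idx])
    comp[comp %in% comp[idx]] <<- tgt
  }
  if (!is.null(clusters) && nrow(clusters) > 0) {
    check_clusters_against_data(data, clusters)
    for (members in cluster_members(clusters)) {
      labs <- unique(data$items$instrument[match(members, data$items$item_id)])
      if (length(labs) > 1) merge_comp(labs)
    }
  }
  groups <- split(instruments, comp)
  names(groups) <- NULL
  structure(
    list(components = groups, n_components = length(groups),
         linked = length(groups) == 1),
    class = "connectivity_report"
  )
}

#' @export
print.connectivity_report <- function(x, ...) {
  cat("Design connectivity:", x$n_components, "component(s)\n")
  for (i in seq_along(x$components)) {
    cat("  [", i, "] ", paste(x$components[[i]], collapse = ", "), "\n", sep = "")
  }
  if (!x$linked) cat("WARNING: instruments are not all linked;",
                     "constrained calibration is not identified across components\n")
  invisible(x)
}

#' Restrict complete data to an incomplete multi-instrument design
#'
#' Keeps, for every person, only the responses to items of the instrument the
#' person is assigned to. This mimics field designs where each respondent is
#' administered a single instrument.
#'
#' @param data a [response_matrix] (typically complete).
#' @param assignment named character vector, person id -> instrument label;
#'   must cover every person in `data`.
#' @return A [response_matrix] with the retained records. Items left without
#'   any response are dropped with a warning.
#' @export
to_incomplete_design <- function(data, assignment) {
  stopifnot(inherits(data, "response_matrix"))
  if (!all(data$persons %in% names(assignment))) {
    stop("assignment does not cover all persons")
  }
  instruments <- unique(data$items$instrument)
  bad <- setdiff(unique(assignment[data$persons]), instruments)
  if (length(bad) > 0) {
    stop("assignment to unknown instrument(s): ", paste(bad, collapse = ", "))
  }
  rec <- data$records
  keep <- rec$instrument == assignment[rec$person_id]
  kept <- rec[keep, , drop = FALSE]
  dropped_items <- setdiff(data$items$item_id, unique(kept$item_id))
  if (length(dropped_items) > 0) {
    warning(length(dropped_items),
            " item(s) left without responses were dropped: ",
            paste(utils::head(dropped_items, 8), collapse = ", "),
            if (length(dropped_items) > 8) ", ..." else "")
  }
  response_matrix(kept)
}
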