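#' Read and write long-format response files
#'
#' The on-disk format is CSV with header `person_id,item_id,score,instrument`;
#' `score` is strictly 0/1. Malformed rows are reported with their line number
#' (header = line 1).
#'
#' @param path file path.
#' @return `read_responses()` returns a [response_matrix].
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("person_id", "item_id", "score", "instrument")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("response file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  bad <- which(!(df$score %in% c("0", "1")))
  if (length(bad) > 0) {
    stop("non-binary score in ", path, " at line(s): ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  }
  df$score <- as.integer(df$score)
  dup <- which(duplicated(df[c("person_id", "item_id")]))
  if (length(dup) > 0) {
    stop("duplicate (person, item) in ", path, " at line(s): ",
         paste(utils::head(dup + 1L, 5), collapse = ", "))
  }
  response_matrix(df)
}

#' @param data a [response_matrix].
#' @rdname read_responses
#' @export
write_responses <- function(data, path) {
  stopifnot(inherits(data, "response_matrix"))
  utils::write.csv(data$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write equate-cluster definition files
#'
#' CSV with header `cluster_id,item_id,active`; `active` is `true`/`false`.
#'
#' @param path file path.
#' @param data optional [response_matrix]; when supplied, cluster members that
#'   do not exist in the data raise an error listing the orphan ids.
#' @return `read_clusters()` returns an [equate_clusters] object.
#' @export
read_clusters <- function(path, data = NULL) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  cl <- equate_clusters(df)
  if (!is.null(data)) check_clusters_against_data(data, cl)
  cl
}

#' @param clusters an [equate_clusters] object.
#' @rdname read_clusters
#' @export
write_clusters <- function(clusters, path) {
  df <- as.data.frame(clusters)
  df$active <- ifelse(df$active, "true", "false")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write a calibration key
#'
#' A key is the frozen product of a calibration: item difficulties in logits,
#' the basis for all subsequent scoring. On disk it is a CSV with columns
#' `item_id,instrument,difficulty,cluster_id` plus a JSON sidecar
#' (`<path>.json`) holding calibration metadata (date, constraint set,
#' convergence information). Difficulties are written at full precision.
#'
#' @param path file path of the CSV part.
#' @return `read_key()` returns a `rasch_key` data.frame with the sidecar
#'   metadata attached as attribute `"meta"` when present.
#' @export
read_key <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("item_id", "instrument", "difficulty", "cluster_id")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("key file ", path, " is missing column(s): ", paste(miss, collapse = ", "))
  }
  df$difficulty <- as.numeric(df$difficulty)
  if (any(!is.finite(df$difficulty))) {
    stop("non-finite difficulty in key file ", path)
  }
  df$cluster_id[df$cluster_id == ""] <- NA_character_
  key <- new_key(df)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    attr(key, "meta") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  key
}

#' @param key a `rasch_key` (from [rasch_fit()] or [read_key()]).
#' @rdname read_key
#' @export
write_key <- function(key, path) {
  stopifnot(inherits(key, "rasch_key"))
  df <- as.data.frame(key)
  df$difficulty <- format(df$difficulty, digits = 17, trim = TRUE)
  df$cluster_id[is.na(df$cluster_id)] <- ""
  utils::write.csv(df[c("item_id", "instrument", "difficulty", "cluster_id")],
                   path, row.names = FALSE, quote = FALSE)
  meta <- attr(key, "meta")
  if (is.null(meta)) meta <- list()
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

new_key <- function(df, meta = NULL) {
  stopifnot(all(c("item_id", "instrument", "difficulty", "cluster_id") %in% names(df)))
  rownames(df) <- NULL
  structure(df, class = c("rasch_key", "data.frame"), meta = meta)
}

#' @export
print.rasch_key <- function(x, ...) {
  cat("Calibration key:", nrow(x), "items,",
      length(unique(x$instrument)), "instrument(s)\n")
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more items\n")
  invisible(x)
}

key_lookup <- function(key, item_ids) {
  idx <- match(item_ids, key$item_id)
  if (anyNA(idx)) {
    stop("item(s) missing from key: ",
         paste(utils::head(item_ids[is.na(idx)], 8), collapse = ", "))
  }
  key$difficulty[idx]
}
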