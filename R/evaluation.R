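#' Relevant-retrieved and ground-truth counts for one ranked result
#'
#' @param result a \code{ranked_result} from [query_db()].
#' @param labels class labels named by image id, covering the query and all
#'   database images.
#' @return list with \code{r} (retrieved ids in the top eta sharing the
#'   query's class) and \code{g} (database images of that class, including
#'   the query when it is a database member).
#' @export
per_query_counts <- function(result, labels) {
  stopifnot(inherits(result, "ranked_result"))
  need <- c(result$query_id, result$ranked_ids)
  missing <- setdiff(need, names(labels))
  if (length(missing)) {
    stop("no label for: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  qcls <- labels[[result$query_id]]
  list(r = sum(labels[result$ranked_ids] == qcls),
       g = sum(labels == qcls))
}

#' Aggregate retrieval metrics over a set of queries
#'
#' Computes the four standard retrieval rates, each on the 0-100 scale:
#' \describe{
#'   \item{avgP}{mean over queries of (relevant retrieved) / eta.}
#'   \item{avgR}{mean over queries of (relevant retrieved) / (relevant in
#'     database).}
#'   \item{Fscore}{harmonic mean of avgP and avgR.}
#'   \item{MavgP}{mean average precision: per query, the sum over relevant
#'     ranks \code{k <= eta} of (relevant so far)/k, divided by the number of
#'     relevant database images, then averaged over queries.}
#' }
#'
#' @param runs list of \code{ranked_result} objects, all at the same depth.
#' @param labels class labels named by image id (queries and database).
#' @param eta retrieval depth; must match every run.
#' @return object of class \code{metrics_report}: list with \code{avgP},
#'   \code{avgR}, \code{Fscore}, \code{MavgP}, \code{eta}, \code{omega}.
#' @export
aggregate_metrics <- function(runs, labels, eta) {
  if (!length(runs)) stop("no queries", call. = FALSE)
  eta <- as.integer(eta)
  if (!all(vapply(runs, function(x) identical(x$eta, eta), logical(1)))) {
    stop("all runs must share the same `eta`", call. = FALSE)
  }
  p <- r <- ap <- numeric(length(runs))
  for (i in seq_along(runs)) {
    run <- runs[[i]]
    cnt <- per_query_counts(run, labels)
    p[i] <- cnt$r / eta
    r[i] <- cnt$r / cnt$g
    rel <- labels[run$ranked_ids] == labels[[run$query_id]]
    ap[i] <- sum((cumsum(rel) / seq_along(rel))[rel]) / cnt$g
  }
  avgP <- 100 * mean(p)
  avgR <- 100 * mean(r)
  fs <- if (avgP + avgR > 0) 2 * avgP * avgR / (avgP + avgR) else 0
  structure(list(avgP = avgP, avgR = avgR, Fscore = fs,
                 MavgP = 100 * mean(ap), eta = eta, omega = length(runs)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> omega = %d queries, eta = %d\n  avgP %.2f%%  avgR %.2f%%  Fscore %.2f%%  MavgP %.2f%%\n",
    x$omega, x$eta, x$avgP, x$avgR, x$Fscore, x$MavgP))
  invisible(x)
}

#' Coefficient of variation of a set of rates
#'
#' Population standard deviation divided by the mean. Used to quantify how
#' stable a retrieval rate is between the noise-free and noisy conditions: a
#' smaller value means the method's performance moves less when queries are
#' corrupted.
#'
#' @param values non-empty numeric vector with non-zero mean.
#' @return non-negative scalar.
#' @examples
#' coefficient_of_variation(c(1, 3)) # 0.5
#' @export
coefficient_of_variation <- function(values) {
  if (!length(values)) stop("`values` must be non-empty", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("coefficient of variation undefined for zero mean",
                   call. = FALSE)
  n <- length(values)
  sqrt(sum((values - m)^2) / n) / m
}

#' Evaluate every query of a set against a feature database
#'
#' Convenience wrapper: runs [query_db()] for each query descriptor and
#' aggregates the metrics.
#'
#' @param db a [feature_db()].
#' @param queries numeric matrix of query descriptors (rownames = query
#'   ids) or \code{NULL} to use every database image as its own query.
#' @param labels class labels named by id for database images and queries;
#'   defaults to the database labels.
#' @param eta retrieval depth.
#' @param exclude_self drop each query's own id from its candidates.
#' @return a \code{metrics_report}.
#' @export
evaluate_retrieval <- function(db, queries = NULL, labels = NULL, eta,
                               exclude_self = FALSE) {
  stopifnot(inherits(db, "feature_db"))
  if (is.null(queries)) queries <- db$features
  if (is.null(labels)) labels <- db$labels
  runs <- lapply(rownames(queries), function(id) {
    query_db(db, queries[id, ], eta = eta, query_id = id,
             exclude_self = exclude_self)
  })
  aggregate_metrics(runs, labels, eta)
}
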