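#' Extended Canberra distance between two histogram descriptors
#'
#' \deqn{D(a, b) = \sum_\tau \frac{|a_\tau - b_\tau|}{a_\tau + \bar a +
#' b_\tau + \bar b}}
#' where \eqn{\bar a}, \eqn{\bar b} are the vector means. Adding the means to
#' the denominators keeps near-empty bins from dominating the plain Canberra
#' distance. Terms with a zero denominator (only possible when both vectors
#' are identically zero) contribute 0. The distance is symmetric,
#' non-negative, zero on identical vectors, and every term lies in [0, 1),
#' so the total is bounded by the dimension.
#'
#' @param a,b non-negative numeric vectors of equal length.
#' @return non-negative scalar.
#' @examples
#' extended_canberra(c(1, 0), c(0, 1)) # 1
#' @export
extended_canberra <- function(a, b) {
  if (length(a) != length(b)) {
    stop("descriptors have different lengths", call. = FALSE)
  }
  a <- as.numeric(a); b <- as.numeric(b)
  if (any(a < 0) || any(b < 0)) {
    stop("descriptors must be non-negative", call. = FALSE)
  }
  den <- a + mean(a) + b + mean(b)
  num <- abs(a - b)
  sum(ifelse(den > 0, num / den, 0))
}

#' Assemble a feature database for retrieval
#'
#' @param features numeric matrix, one row per image, rownames = image ids
#'   (e.g. from [read_feature_store()]).
#' @param labels class labels, either named by image id or in row order.
#' @return object of class \code{feature_db}.
#' @export
feature_db <- function(features, labels) {
  features <- as.matrix(features)
  if (is.null(rownames(features))) {
    stop("`features` must have image ids as rownames", call. = FALSE)
  }
  if (anyDuplicated(rownames(features))) {
    stop("image ids must be unique", call. = FALSE)
  }
  if (!is.null(names(labels))) {
    missing <- setdiff(rownames(features), names(labels))
    if (length(missing)) {
      stop("no label for image(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    labels <- labels[rownames(features)]
  } else if (length(labels) != nrow(features)) {
    stop("`labels` length must match the number of images", call. = FALSE)
  }
  labels <- as.character(labels)
  names(labels) <- rownames(features)
  structure(list(features = features, labels = labels,
                 dim = ncol(features)),
            class = "feature_db")
}

#' @export
print.feature_db <- function(x, ...) {
  cat(sprintf("<feature_db> %d images, %d-dim descriptors, %d classes\n",
              nrow(x$features), x$dim, length(unique(x$labels))))
  invisible(x)
}

#' Rank database images against a query descriptor
#'
#' Scores every database image with the extended Canberra distance to the
#' query and returns the \code{eta} nearest, sorted by ascending distance
#' with deterministic lexicographic tie-break on image id. A query that is
#' itself a database member self-matches at distance 0 and ranks first
#' unless \code{exclude_self} removes its id.
#'
#' @param db a [feature_db()].
#' @param q query descriptor (length \code{db$dim}).
#' @param eta retrieval depth, \code{1 <= eta <=} database size.
#' @param query_id id of the query image (used for \code{exclude_self} and
#'   reporting).
#' @param exclude_self drop the query's own id from the candidates.
#' @return object of class \code{ranked_result}: list with \code{query_id},
#'   \code{ranked_ids}, \code{distances}, \code{eta}.
#' @export
query_db <- function(db, q, eta, query_id = NA_character_,
                     exclude_self = FALSE) {
  stopifnot(inherits(db, "feature_db"))
  if (length(q) != db$dim) {
    stop(sprintf("query has %d dims, database has %d", length(q), db$dim),
         call. = FALSE)
  }
  ids <- rownames(db$features)
  if (exclude_self && !is.na(query_id)) {
    keep <- ids != query_id
    ids <- ids[keep]
  } else {
    keep <- rep(TRUE, length(ids))
  }
  if (!length(ids)) stop("empty database", call. = FALSE)
  eta <- as.integer(eta)
  if (eta < 1L || eta > length(ids)) {
    stop("`eta` must be between 1 and the database size", call. = FALSE)
  }
  d <- apply(db$features[keep, , drop = FALSE], 1L, extended_canberra,
             b = as.numeric(q))
  ord <- order(d, ids, method = "radix")[seq_len(eta)]
  structure(list(query_id = query_id, ranked_ids = ids[ord],
                 distances = unname(d[ord]), eta = eta),
            class = "ranked_result")
}

#' @export
print.ranked_result <- function(x, ...) {
  cat(sprintf("<ranked_result> query %s, top %d of distances [%.4g, %.4g]\n",
              x$query_id, x$eta, min(x$distances), max(x$distances)))
  invisible(x)
}
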