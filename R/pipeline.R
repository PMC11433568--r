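#' Run configuration for the extraction / retrieval pipeline
#'
#' Bundles every tunable of the pipeline so a run is reproducible from
#' (inputs, config, seed). \code{scales = NULL} defers to
#' [default_scales()] per image size at extraction time.
#'
#' @param w odd local-mean window (pixels) for the neutrosophic transform.
#' @param scales integer vector of scales, or \code{NULL} for the size-based
#'   default.
#' @param normalize per-block probability normalization of histograms.
#' @param eta retrieval depth (top matches kept per query).
#' @param exclude_self drop each query's own id from its result list.
#' @param seed integer seed driving all randomness of a run.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(w = 3L, scales = NULL, normalize = TRUE, eta = 100L,
                       exclude_self = FALSE, seed = 1L) {
  structure(list(w = as.integer(w), scales = scales,
                 normalize = isTRUE(normalize), eta = as.integer(eta),
                 exclude_self = isTRUE(exclude_self),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Save / load a run configuration as JSON
#'
#' @param config a [run_config()].
#' @param path JSON file path.
#' @return \code{path} (write) or a \code{run_config} (read).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(w = x$w, scales = x$scales, normalize = x$normalize,
             eta = x$eta, exclude_self = x$exclude_self, seed = x$seed)
}

#' Extract descriptors for a set of images into a feature matrix
#'
#' @param images named list of grayscale matrices.
#' @param config a [run_config()].
#' @return numeric matrix, one row per image (rownames = ids), with the
#'   resolved scales in attribute \code{scales}.
#' @export
extract_features <- function(images, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  scales <- config$scales
  if (is.null(scales)) scales <- default_scales(dim(images[[1L]]))
  rows <- lapply(images, function(img) {
    as.numeric(extract_descriptor(img, scales = scales, w = config$w,
                                  normalize = config$normalize))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(images)
  colnames(m) <- descriptor_names(scales)
  structure(m, scales = scales)
}

#' Extract descriptors for a labeled image directory into a feature store
#'
#' Reads the manifest written by [write_dataset()], extracts one descriptor
#' row per image, and writes the CSV feature store with its JSON sidecar.
#' The run is resumable: ids already present in an existing store are
#' skipped and the remaining rows appended.
#'
#' @param dir labeled image directory (\code{labels.csv} + images).
#' @param out output CSV path.
#' @param config a [run_config()].
#' @return the store path, invisibly.
#' @export
run_extract <- function(dir, out, config = run_config()) {
  ds <- read_dataset(dir)
  done <- character(0)
  if (file.exists(out)) done <- rownames(read_feature_store(out))
  todo <- setdiff(names(ds$images), done)
  if (length(todo) == 0L) return(invisible(out))
  feats <- extract_features(ds$images[todo], config)
  if (length(done)) {
    feats <- rbind(read_feature_store(out), feats)
  }
  write_feature_store(feats, out, w = config$w,
                      scales = attr(feats, "scales") %||% config$scales,
                      normalize = config$normalize)
  invisible(out)
}

#' End-to-end retrieval benchmark on a labeled dataset
#'
#' Extracts descriptors for the clean images, evaluates all-queries
#' retrieval on the clean database, then (optionally) corrupts every image
#' with additive white Gaussian noise, re-queries the clean database with
#' the noisy descriptors, and reports the coefficient of variation of each
#' rate across the two conditions. \code{eta} is capped at the database
#' size.
#'
#' @param dataset a \code{synthetic_dataset} (from
#'   [generate_texture_dataset()] or [read_dataset()]).
#' @param config a [run_config()].
#' @param noise a [noise_spec()], or \code{NULL} to skip the noisy pass.
#' @return list with \code{clean} and (when noise is run) \code{noisy}
#'   \code{metrics_report}s plus \code{cv}, the per-rate coefficient of
#'   variation across conditions.
#' @export
run_benchmark <- function(dataset, config = run_config(),
                          noise = noise_spec()) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  eta <- min(config$eta, length(dataset$images))
  clean_feats <- extract_features(dataset$images, config)
  db <- feature_db(clean_feats, dataset$labels)
  clean <- evaluate_retrieval(db, eta = eta,
                              exclude_self = config$exclude_self)
  out <- list(clean = clean)
  if (!is.null(noise)) {
    spec <- noise_spec(noise$sigma_min, noise$sigma_max,
                       seed = noise$seed %||% (config$seed + 1L))
    proto <- build_noisy_query_protocol(dataset, spec)
    noisy_feats <- extract_features(proto$queries$images, config)
    noisy <- evaluate_retrieval(db, queries = noisy_feats,
                                labels = dataset$labels, eta = eta,
                                exclude_self = config$exclude_self)
    out$noisy <- noisy
    out$cv <- vapply(c("avgP", "avgR", "Fscore", "MavgP"), function(k) {
      coefficient_of_variation(c(clean[[k]], noisy[[k]]))
    }, numeric(1))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
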