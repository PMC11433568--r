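#' Joint histogram of a primary pattern map with the binary RiTxP map
#'
#' Co-occurrence counts of a 10-label map (MsTrP or NrTxP) with the 2-label
#' RiTxP map over the shared valid region. Bin index (0-based) is
#' \code{primary_label * 2 + ri_label}, so the RiTxP label varies fastest.
#'
#' @param primary integer matrix with labels in 0..9 (-1 marks invalid).
#' @param ri integer matrix with labels in \{0, 1\} (-1 marks invalid).
#' @return numeric vector of 20 counts with attribute \code{pixel_count}.
#' @export
joint_histogram <- function(primary, ri) {
  if (!identical(dim(primary), dim(ri))) {
    stop("label maps have different shapes", call. = FALSE)
  }
  ok <- primary >= 0L & ri >= 0L
  if (!identical(primary >= 0L, ri >= 0L)) {
    stop("label maps have different valid regions", call. = FALSE)
  }
  idx <- primary[ok] * 2L + ri[ok]
  counts <- tabulate(idx + 1L, nbins = 20L)
  structure(as.numeric(counts), pixel_count = sum(ok))
}

#' Single-scale 40-bin descriptor of one image channel
#'
#' Computes the three pattern maps at scale \code{r}, then concatenates the
#' MsTrP x RiTxP joint histogram (20 bins) with the NrTxP x RiTxP joint
#' histogram (20 bins). With \code{normalize = TRUE} each 20-bin block is
#' divided by its pixel count, giving two probability histograms.
#'
#' @param channel numeric matrix (a neutrosophic channel, or any grayscale
#'   image).
#' @param r positive integer scale.
#' @param normalize divide each 20-bin block by the number of contributing
#'   pixels (default \code{TRUE}).
#' @return numeric vector of length 40.
#' @export
scale_descriptor <- function(channel, r, normalize = TRUE) {
  maps <- pattern_maps(channel, r)
  ms <- joint_histogram(maps$mstrp, maps$ritxp)
  nr <- joint_histogram(maps$nrtxp, maps$ritxp)
  if (normalize) {
    ms <- ms / attr(ms, "pixel_count")
    nr <- nr / attr(nr, "pixel_count")
  }
  c(as.numeric(ms), as.numeric(nr))
}

#' Full multi-scale MsNrRiTxP descriptor of a grayscale image
#'
#' Transforms the image into its neutrosophic triplet, then for each scale
#' \code{r} (in order) and each channel T, I, F (in that order) appends the
#' 40-bin single-scale descriptor, for a total length of \code{120 * S}.
#'
#' @param image numeric matrix of intensities.
#' @param scales integer vector of scales; default chosen by
#'   [default_scales()] from the image size.
#' @param w odd local-mean window for the neutrosophic transform.
#' @param normalize per-block probability normalization (default
#'   \code{TRUE}).
#' @return named numeric vector of length \code{120 * length(scales)} with
#'   attributes \code{scales}, \code{w} and \code{normalized}. Names follow
#'   \code{s{r}_{T|I|F}_{ms|nr}_{p}_{q}} with \code{p} the primary label and
#'   \code{q} the RiTxP label.
#' @examples
#' img <- matrix(runif(32 * 32, 0, 255), 32, 32)
#' d <- extract_descriptor(img, scales = 1:2)
#' length(d) # 240
#' @export
extract_descriptor <- function(image, scales = NULL, w = 3L,
                               normalize = TRUE) {
  image <- as_gray_matrix(image)
  if (is.null(scales)) scales <- default_scales(dim(image))
  scales <- vapply(scales, check_scale, integer(1))
  rmax <- max(scales)
  if (min(dim(image)) < 2L * rmax + 1L) {
    stop(sprintf("scale r = %d too large for a %d x %d image", rmax,
                 nrow(image), ncol(image)), call. = FALSE)
  }
  ns <- to_neutrosophic(image, w)
  out <- unlist(lapply(scales, function(r) {
    unlist(lapply(c("T", "I", "F"), function(ch) {
      scale_descriptor(ns[[ch]], r, normalize = normalize)
    }), use.names = FALSE)
  }), use.names = FALSE)
  names(out) <- descriptor_names(scales)
  structure(out, scales = scales, w = as.integer(w),
            normalized = isTRUE(normalize))
}

#' Default scale set for an image size
#'
#' Nine scales (r = 1..9) for images whose shorter side is at least 64
#' pixels, five scales (r = 1..5) for smaller images. The cutoff keeps the
#' valid region a usable fraction of small images.
#'
#' @param dim image dimensions \code{c(rows, cols)}.
#' @return integer vector of scales.
#' @export
default_scales <- function(dim) {
  if (min(dim) >= 64L) 1:9 else 1:5
}

descriptor_names <- function(scales) {
  unlist(lapply(scales, function(r) {
    unlist(lapply(c("T", "I", "F"), function(ch) {
      unlist(lapply(c("ms", "nr"), function(blk) {
        sprintf("s%d_%s_%s_%d_%d", r, ch, blk, rep(0:9, each = 2L), 0:1)
      }))
    }))
  }))
}

#' Write a feature store to CSV with a JSON sidecar
#'
#' One row per image, \code{image_id} first, then one column per descriptor
#' bin. Values are written with 17 significant digits so a
#' write-read-write cycle is byte-identical. The sidecar
#' (\code{<path>.json}) records the window, scales, normalization flag and
#' package version.
#'
#' @param features numeric matrix (rows = images) with rownames as image ids
#'   and colnames as bin names, or a list of descriptors from
#'   [extract_descriptor()] (named by image id).
#' @param path output CSV path.
#' @param w,scales,normalize extraction parameters recorded in the sidecar;
#'   taken from descriptor attributes when \code{features} is a list.
#' @return \code{path}, invisibly.
#' @export
write_feature_store <- function(features, path, w = NULL, scales = NULL,
                                normalize = NULL) {
  if (is.list(features) && !is.data.frame(features)) {
    first <- features[[1L]]
    if (is.null(w)) w <- attr(first, "w")
    if (is.null(scales)) scales <- attr(first, "scales")
    if (is.null(normalize)) normalize <- attr(first, "normalized")
    ids <- names(features)
    features <- do.call(rbind, lapply(features, as.numeric))
    rownames(features) <- ids
    colnames(features) <- descriptor_names(scales)
  }
  if (anyDuplicated(rownames(features))) {
    stop("duplicate image ids in feature store", call. = FALSE)
  }
  lines <- c(
    paste(c("image_id", colnames(features)), collapse = ","),
    vapply(seq_len(nrow(features)), function(i) {
      paste(c(rownames(features)[i], sprintf("%.17g", features[i, ])),
            collapse = ",")
    }, character(1))
  )
  writeLines(lines, path)
  meta <- list(w = w, scales = scales, normalize = normalize,
               version = as.character(utils::packageVersion("neutrotex")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a feature store written by [write_feature_store()]
#'
#' @param path CSV path.
#' @return numeric matrix with image ids as rownames, bin names as colnames,
#'   and the sidecar metadata (if present) in attribute \code{meta}.
#' @export
read_feature_store <- function(path) {
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
  structure(m, meta = meta)
}
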