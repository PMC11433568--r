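#' Sample a circular neighborhood around a pixel
#'
#' Samples \code{8r} points evenly spaced on the circle of radius \code{r}
#' centered at pixel \code{(i, j)} (1-based row/column). Sample \code{n}
#' (0-based) sits at offset \code{(-r sin theta, r cos theta)} with
#' \code{theta = 2 pi n / (8 r)}, so sample 0 lies due east and the index
#' runs counter-clockwise in image coordinates. Off-grid positions are
#' bilinearly interpolated; positions within 1e-6 of a grid point take that
#' pixel's exact value.
#'
#' @param image numeric matrix.
#' @param i,j center row and column (1-based); must lie in the valid region
#'   \code{[1 + r, nrow - r] x [1 + r, ncol - r]} unless \code{clamp_border}.
#' @param r positive integer scale (circle radius in pixels).
#' @param clamp_border if \code{TRUE}, sample with replicate padding instead
#'   of erroring near the border (used internally for the full-grid
#'   mean-local-difference image).
#' @return a \code{circular_neighborhood}: list with \code{samples}
#'   (length \code{8r}), \code{center} (the value at \code{(i, j)}) and
#'   \code{r}.
#' @export
sample_circle <- function(image, i, j, r, clamp_border = FALSE) {
  image <- as_gray_matrix(image)
  r <- check_scale(r)
  s <- .sample_circle_cpp(image, as.integer(i), as.integer(j), r,
                          isTRUE(clamp_border))
  structure(list(samples = s, center = image[i, j], r = r),
            class = "circular_neighborhood")
}

#' Median quantization of a circular neighborhood
#'
#' Collapses the \code{8r} samples to 8 values: element \code{k} (0-based) is
#' the median of the arc of \code{r} consecutive samples starting at index
#' \code{r k}. Even-sized arcs use the mean of the two middle order
#' statistics. Medians along the arc reject isolated noisy samples, which is
#' what makes the resulting pattern noise-tolerant.
#'
#' @param nb a \code{circular_neighborhood} from [sample_circle()].
#' @return numeric vector of length 8.
#' @export
median_quantize <- function(nb) {
  stopifnot(inherits(nb, "circular_neighborhood"))
  r <- nb$r
  vapply(0:7, function(k) median(nb$samples[(r * k + 1):(r * k + r)]),
         numeric(1))
}

#' Mean absolute local differences of a circular neighborhood
#'
#' Element \code{k} (0-based) is the mean of \code{|sample - center|} over
#' the arc of \code{r} consecutive samples starting at index \code{r k}.
#' Averaging the absolute differences along the arc damps pixel-level noise.
#'
#' @inheritParams median_quantize
#' @return non-negative numeric vector of length 8.
#' @export
mean_local_difference_quantize <- function(nb) {
  stopifnot(inherits(nb, "circular_neighborhood"))
  r <- nb$r
  d <- abs(nb$samples - nb$center)
  vapply(0:7, function(k) mean(d[(r * k + 1):(r * k + r)]), numeric(1))
}

#' Circular uniformity of an 8-bit pattern
#'
#' Counts the 0/1 transitions around the 8 bits, including the wraparound
#' pair.
#'
#' @param bits vector of exactly 8 values in \{0, 1\}.
#' @return integer transition count in \{0, 2, 4, 6, 8\}.
#' @examples
#' uniformity(c(0, 0, 0, 0, 1, 1, 1, 1)) # 2
#' @export
uniformity <- function(bits) {
  bits <- check_bits(bits)
  sum(abs(diff(c(bits, bits[1L]))))
}

#' Rotation-invariant uniform (riu2) label of an 8-bit pattern
#'
#' Patterns with at most two circular transitions receive their number of
#' 1-bits (0..8); all other patterns share the label 9, giving 10 labels in
#' total, each invariant to circular shifts of the bits.
#'
#' @inheritParams uniformity
#' @return integer label in 0..9.
#' @examples
#' riu2_label(c(0, 0, 0, 0, 1, 1, 1, 1)) # 4
#' riu2_label(c(0, 1, 0, 1, 0, 1, 0, 1)) # 9
#' @export
riu2_label <- function(bits) {
  bits <- check_bits(bits)
  if (uniformity(bits) <= 2L) sum(bits) else 9L
}

#' Per-pixel texture pattern maps at one scale
#'
#' Computes, for every pixel in the valid region
#' \code{[1 + r, M - r] x [1 + r, N - r]}, the three per-pixel labels used by
#' the MsNrRiTxP descriptor:
#' \describe{
#'   \item{MsTrP}{sign of (arc-median sample - center) per arc, read as an
#'     8-bit pattern and mapped through riu2 (labels 0..9).}
#'   \item{NrTxP}{sign of (arc-mean absolute difference - ring threshold
#'     \code{nu_r}) per arc, riu2-mapped (labels 0..9). \code{nu_r} is the
#'     mean, over the \code{8r} pixels of the square ring at Chebyshev
#'     distance \code{r}, of the full-grid mean-absolute-local-difference
#'     image.}
#'   \item{RiTxP}{binary: 1 when the center is at least the mean image value
#'     over the same square ring, else 0.}
#' }
#' All sign comparisons treat an exact tie as 1. Pixels outside the valid
#' region carry the sentinel label -1 and are excluded from histograms.
#'
#' @param image numeric matrix (typically one neutrosophic channel).
#' @param r positive integer scale.
#' @return list of class \code{pattern_maps} with integer matrices
#'   \code{mstrp}, \code{nrtxp}, \code{ritxp} and the scale \code{r}.
#' @export
pattern_maps <- function(image, r) {
  image <- as_gray_matrix(image)
  r <- check_scale(r)
  if (nrow(image) < 2L * r + 1L || ncol(image) < 2L * r + 1L) {
    stop(sprintf("image (%d x %d) too small for scale r = %d",
                 nrow(image), ncol(image), r), call. = FALSE)
  }
  maps <- .pattern_maps_cpp(image, r)
  structure(c(maps, list(r = r)), class = "pattern_maps")
}

#' @rdname pattern_maps
#' @export
compute_mstrp_map <- function(image, r) pattern_maps(image, r)$mstrp

#' @rdname pattern_maps
#' @export
compute_nrtxp_map <- function(image, r) pattern_maps(image, r)$nrtxp

#' @rdname pattern_maps
#' @export
compute_ritxp_map <- function(image, r) pattern_maps(image, r)$ritxp

check_scale <- function(r) {
  if (length(r) != 1L || !is.finite(r) || r != as.integer(r) || r < 1L) {
    stop("scale `r` must be a positive integer", call. = FALSE)
  }
  as.integer(r)
}

check_bits <- function(bits) {
  if (length(bits) != 8L || !all(bits %in% c(0, 1))) {
    stop("`bits` must be 8 values in {0, 1}", call. = FALSE)
  }
  as.integer(bits)
}
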