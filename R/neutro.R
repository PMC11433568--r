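#' Local box mean of a grayscale image
#'
#' Mean intensity in the \code{w x w} window centered at each pixel, with
#' replicate padding at the borders so the output covers the full grid.
#'
#' @param image numeric matrix of intensities (any non-negative scale).
#' @param w odd window side length in pixels, \code{w >= 3}.
#' @return numeric matrix of the same dimensions as \code{image}.
#' @examples
#' m <- matrix(0, 3, 3); m[2, 2] <- 9
#' local_mean(m, 3)[2, 2] # 1
#' @export
local_mean <- function(image, w = 3L) {
  image <- as_gray_matrix(image)
  if (length(w) != 1L || !is.finite(w) || w != as.integer(w) || w < 3L ||
      w %% 2L == 0L) {
    stop("`w` must be an odd integer >= 3", call. = FALSE)
  }
  w <- as.integer(w)
  M <- nrow(image); N <- ncol(image)
  h <- (w - 1L) %/% 2L
  out <- matrix(0, M, N)
  for (a in -h:h) {
    ri <- pmin(pmax(seq_len(M) + a, 1L), M)
    for (b in -h:h) {
      ci <- pmin(pmax(seq_len(N) + b, 1L), N)
      out <- out + image[ri, ci, drop = FALSE]
    }
  }
  out / (w * w)
}

#' Transform a grayscale image into the neutrosophic domain
#'
#' Decomposes an image into truth (T), indeterminacy (I) and falsity (F)
#' membership images. T is the min-max normalization of the \code{w x w}
#' local-mean image; I is the min-max normalization of the absolute deviation
#' of each pixel from its local mean; F is the complement \code{1 - T}.
#' When a channel's normalization denominator is zero (a constant local-mean
#' or deviation image) that channel is set to 0 everywhere and a warning is
#' issued, so downstream pattern maps stay defined.
#'
#' @inheritParams local_mean
#' @return an object of class \code{neutro_triplet}: a list with numeric
#'   matrices \code{T}, \code{I}, \code{F} in \code{[0, 1]} and the window
#'   \code{w}.
#' @examples
#' img <- matrix(runif(64, 0, 255), 8, 8)
#' ns <- to_neutrosophic(img, w = 3)
#' range(ns$T); all.equal(ns$F, 1 - ns$T)
#' @export
to_neutrosophic <- function(image, w = 3L) {
  image <- as_gray_matrix(image)
  zbar <- local_mean(image, w)
  T <- minmax_or_zero(zbar, "truth")
  delta <- abs(image - zbar)
  I <- minmax_or_zero(delta, "indeterminacy")
  structure(list(T = T, I = I, F = 1 - T, w = as.integer(w)),
            class = "neutro_triplet")
}

#' @export
print.neutro_triplet <- function(x, ...) {
  cat(sprintf("<neutro_triplet> %d x %d, w = %d\n",
              nrow(x$T), ncol(x$T), x$w))
  invisible(x)
}

minmax_or_zero <- function(m, what) {
  lo <- min(m); hi <- max(m)
  if (hi - lo <= 0) {
    warning(sprintf("degenerate %s channel (constant); set to 0", what),
            call. = FALSE)
    return(matrix(0, nrow(m), ncol(m)))
  }
  (m - lo) / (hi - lo)
}

# Validate and promote an image to a double matrix.
as_gray_matrix <- function(image) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(image) < 3L || ncol(image) < 3L) {
    stop("`image` must be at least 3 x 3", call. = FALSE)
  }
  if (any(!is.finite(image)) || any(image < 0)) {
    stop("`image` intensities must be finite and non-negative", call. = FALSE)
  }
  storage.mode(image) <- "double"
  image
}
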