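#' Generate a labeled synthetic texture dataset
#'
#' Produces multi-class grayscale texture images standing in for a labeled
#' retrieval database. Classes cycle through four parameterized families
#' whose statistics separate both locally and globally:
#' oriented sinusoidal gratings (class-specific frequency and orientation),
#' checkerboards (class-specific period), Gaussian blob fields
#' (class-specific density), and high-frequency gratings. Each image gets
#' random phase/offset/orientation jitter so images within a class differ
#' while keeping the class statistics. Intensities are integers in
#' [0, 255]. Generation is fully determined by \code{seed}.
#'
#' @param n_classes number of texture classes (>= 2).
#' @param n_per_class images per class.
#' @param size image side length in pixels (>= 32).
#' @param seed integer RNG seed.
#' @return object of class \code{synthetic_dataset}: list with
#'   \code{images} (named list of matrices), \code{labels} (named character
#'   vector of class ids) and \code{spec} (the generator parameters).
#' @export
generate_texture_dataset <- function(n_classes, n_per_class, size = 64L,
                                     seed = 1L) {
  if (n_classes < 2L) stop("`n_classes` must be >= 2", call. = FALSE)
  if (n_per_class < 1L) stop("`n_per_class` must be >= 1", call. = FALSE)
  if (size < 32L) stop("`size` must be >= 32", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  images <- list()
  labels <- character(0)
  k <- 0L
  for (cls in seq_len(n_classes)) {
    for (rep in seq_len(n_per_class)) {
      k <- k + 1L
      id <- sprintf("img%04d", k)
      images[[id]] <- synth_texture(cls, size)
      labels[id] <- sprintf("c%d", cls)
    }
  }
  structure(list(images = images, labels = labels,
                 spec = list(n_classes = n_classes,
                             n_per_class = n_per_class,
                             size = as.integer(size),
                             seed = as.integer(seed))),
            class = "synthetic_dataset")
}

# One image of class `cls`: family cycles over gratings, checkerboards,
# blob fields and fine gratings; the cycle count shifts the family parameter
# so classes 5+ stay distinct from classes 1-4.
synth_texture <- function(cls, size) {
  fam <- (cls - 1L) %% 4L
  lvl <- (cls - 1L) %/% 4L
  x <- matrix(rep(seq_len(size), each = size), size, size)  # column index
  y <- matrix(rep(seq_len(size), times = size), size, size) # row index
  if (fam == 0L) {
    # coarse grating: ~0.06 cycles/px, class-tied orientation
    f <- 0.055 + 0.02 * lvl
    ang <- (30 * cls + runif(1, -10, 10)) * pi / 180
    img <- 120 + 85 * sin(2 * pi * f * (x * cos(ang) + y * sin(ang)) +
                            runif(1, 0, 2 * pi))
  } else if (fam == 1L) {
    # checkerboard, period 7 px (+2 per cycle), random sub-period offset
    p <- 7 + 2 * lvl
    ox <- runif(1, 0, p); oy <- runif(1, 0, p)
    img <- ifelse((floor((x + ox) / p) + floor((y + oy) / p)) %% 2 == 0,
                  45, 210)
  } else if (fam == 2L) {
    # blob field: Gaussian bumps at class-tied density on a dark background
    dens <- 0.008 + 0.004 * lvl
    nb <- max(3L, round(dens * size * size))
    img <- matrix(60, size, size)
    cx <- runif(nb, 1, size); cy <- runif(nb, 1, size)
    for (b in seq_len(nb)) {
      img <- img + 160 * exp(-((x - cx[b])^2 + (y - cy[b])^2) / (2 * 2.5^2))
    }
  } else {
    # fine grating: ~0.2 cycles/px, orientation offset from family 0
    f <- 0.19 + 0.03 * lvl
    ang <- (120 + 15 * cls + runif(1, -10, 10)) * pi / 180
    img <- 120 + 85 * sin(2 * pi * f * (x * cos(ang) + y * sin(ang)) +
                            runif(1, 0, 2 * pi))
  }
  matrix(pmin(pmax(round(img), 0), 255), size, size)
}

#' Additive white Gaussian noise specification
#'
#' Per corrupted image, a standard deviation is drawn uniformly from
#' \code{[sigma_min, sigma_max]} (on the 0-255 intensity scale) and i.i.d.
#' zero-mean Gaussian noise of that standard deviation is added, then the
#' result is clipped to [0, 255]. Defaults follow the common noisy-query
#' benchmark range of 5 to 50. Set \code{sigma_min == sigma_max} for a
#' fixed-sigma sweep.
#'
#' @param sigma_min,sigma_max noise standard deviation bounds (intensity
#'   units), \code{0 < sigma_min <= sigma_max}.
#' @param seed optional integer seed used when the spec drives a whole
#'   corruption run.
#' @return object of class \code{noise_spec}.
#' @export
noise_spec <- function(sigma_min = 5, sigma_max = 50, seed = NULL) {
  if (!(sigma_min > 0 && sigma_min <= sigma_max)) {
    stop("need 0 < sigma_min <= sigma_max", call. = FALSE)
  }
  structure(list(sigma_min = sigma_min, sigma_max = sigma_max, seed = seed),
            class = "noise_spec")
}

#' Corrupt one image with additive white Gaussian noise
#'
#' @param image numeric matrix on the 0-255 scale.
#' @param spec a [noise_spec()]; when it carries a seed, the RNG is seeded
#'   before drawing.
#' @return noisy image, clipped to [0, 255].
#' @export
add_awgn <- function(image, spec = noise_spec()) {
  stopifnot(inherits(spec, "noise_spec"))
  image <- as_gray_matrix(image)
  if (!is.null(spec$seed)) set.seed(as.integer(spec$seed))
  sigma <- runif(1, spec$sigma_min, spec$sigma_max)
  noisy <- image + rnorm(length(image), 0, sigma)
  matrix(pmin(pmax(noisy, 0), 255), nrow(image), ncol(image))
}

#' Build the clean-database / noisy-query benchmark protocol
#'
#' The noise-free images form the retrieval database; one noise-corrupted
#' copy of each image (same id, same label) forms the query set, mirroring
#' the standard noise-robustness protocol where clean images are searched
#' with degraded queries.
#'
#' @param dataset a [generate_texture_dataset()] result.
#' @param spec a [noise_spec()]; its seed (default: the dataset seed + 1)
#'   makes the corruption reproducible.
#' @return list with \code{database} (the clean dataset) and \code{queries}
#'   (a \code{synthetic_dataset} of noisy copies with identical ids/labels).
#' @export
build_noisy_query_protocol <- function(dataset, spec = noise_spec()) {
  stopifnot(inherits(dataset, "synthetic_dataset"),
            inherits(spec, "noise_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  seed <- if (!is.null(spec$seed)) spec$seed else dataset$spec$seed + 1L
  set.seed(as.integer(seed))
  per_image <- noise_spec(spec$sigma_min, spec$sigma_max) # no reseeding inside
  noisy <- lapply(dataset$images, add_awgn, spec = per_image)
  queries <- structure(list(images = noisy, labels = dataset$labels,
                            spec = c(dataset$spec,
                                     list(noise = c(spec$sigma_min,
                                                    spec$sigma_max),
                                          noise_seed = seed))),
                       class = "synthetic_dataset")
  list(database = dataset, queries = queries)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d images (%d x %d), %d classes\n",
              length(x$images), x$spec$size, x$spec$size,
              length(unique(x$labels))))
  invisible(x)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
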