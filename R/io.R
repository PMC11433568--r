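#' Read a grayscale image from PNG or TIFF
#'
#' Intensities are promoted to double precision on the 0-255 scale
#' regardless of the file's bit depth. Multi-channel images are rejected
#' unless \code{to_gray = TRUE}, in which case Rec. 709 luminance is taken.
#'
#' @param path path to a \code{.png}, \code{.tif} or \code{.tiff} file.
#' @param to_gray convert RGB(A) input to luminance instead of erroring.
#' @return numeric matrix of intensities in [0, 255].
#' @export
read_gray_image <- function(path, to_gray = FALSE) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(arr)) == 3L) {
    if (!to_gray) {
      stop(path, " has ", dim(arr)[3L],
           " channels; pass to_gray = TRUE for luminance conversion",
           call. = FALSE)
    }
    arr <- 0.2126 * arr[, , 1L] + 0.7152 * arr[, , 2L] + 0.0722 * arr[, , 3L]
  }
  arr * 255
}

#' Write a grayscale matrix as an 8-bit PNG
#'
#' @param image numeric matrix on the 0-255 scale (clipped and rounded).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gray_png <- function(image, path) {
  m <- pmin(pmax(image, 0), 255) / 255
  png::writePNG(m, path)
  invisible(path)
}

#' Write a synthetic dataset as PNGs plus a labels manifest
#'
#' Creates \code{<dir>/<image_id>.png} for every image and
#' \code{<dir>/labels.csv} with columns \code{image_id, class}.
#'
#' @param dataset a [generate_texture_dataset()] result.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(dataset$images)) {
    write_gray_png(dataset$images[[id]], file.path(dir, paste0(id, ".png")))
  }
  manifest <- file.path(dir, "labels.csv")
  write.csv(data.frame(image_id = names(dataset$labels),
                       class = unname(dataset$labels)),
            manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a labeled image directory back into memory
#'
#' Expects the layout written by [write_dataset()]: a \code{labels.csv}
#' manifest (\code{image_id, class}) next to one PNG/TIFF per image id.
#'
#' @param dir directory containing \code{labels.csv} and the images.
#' @param to_gray passed to [read_gray_image()].
#' @return a \code{synthetic_dataset}-shaped list with \code{images} and
#'   \code{labels}.
#' @export
read_dataset <- function(dir, to_gray = FALSE) {
  manifest <- file.path(dir, "labels.csv")
  if (!file.exists(manifest)) {
    stop("no labels.csv manifest in ", dir, call. = FALSE)
  }
  df <- read.csv(manifest, colClasses = "character")
  if (anyDuplicated(df$image_id)) {
    stop("duplicate image ids in manifest", call. = FALSE)
  }
  images <- list()
  for (i in seq_len(nrow(df))) {
    id <- df$image_id[i]
    candidates <- file.path(dir, paste0(id, c(".png", ".tif", ".tiff")))
    hit <- candidates[file.exists(candidates)][1L]
    if (is.na(hit)) stop("no image file for id ", id, call. = FALSE)
    images[[id]] <- read_gray_image(hit, to_gray = to_gray)
  }
  labels <- df$class
  names(labels) <- df$image_id
  sz <- dim(images[[1L]])
  structure(list(images = images, labels = labels,
                 spec = list(n_classes = length(unique(labels)),
                             n_per_class = NA_integer_, size = sz[1L],
                             seed = NA_integer_)),
            class = "synthetic_dataset")
}
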