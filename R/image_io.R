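#' Read a grayscale image
#'
#' Reads a PNG, TIFF, or single-slice NIfTI image and returns an integer
#' intensity matrix in \[0, 255\]. Color images are converted to luminance
#' (0.2126 R + 0.7152 G + 0.0722 B). Inputs whose values are already integers
#' in \[0, 255\] (ordinary 8-bit images) are preserved exactly; anything else
#' (16-bit data, float NIfTI slices) is rescaled by its own min--max onto
#' \[0, 255\] via [normalize_quantize()].
#'
#' @param path Path to a `.png`, `.tif`/`.tiff`, or `.nii`/`.nii.gz` file.
#' @param slice For a 3D NIfTI volume, which axial slice to extract
#'   (default: the middle slice).
#' @return An integer matrix (rows x cols) of gray levels in \[0, 255\].
#' @seealso [write_image()], [normalize_quantize()]
#' @export
load_image <- function(path, slice = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  raw <- switch(ext,
    png = {
      a <- png::readPNG(path)
      to_luminance(a) * 255
    },
    tif = ,
    tiff = {
      a <- tiff::readTIFF(path, as.is = TRUE)
      to_luminance(a)
    },
    nii = {
      a <- as.array(RNifti::readNifti(path))
      a <- drop(a)
      if (length(dim(a)) == 3L) {
        if (is.null(slice)) slice <- ceiling(dim(a)[3] / 2)
        a <- a[, , slice]
      }
      if (length(dim(a)) != 2L) {
        stop("NIfTI input must be a 2D slice (or 3D with `slice` given)",
             call. = FALSE)
      }
      a
    },
    stop(sprintf("unsupported image format: .%s (%s)", ext, path), call. = FALSE)
  )
  if (length(raw) == 0L) {
    stop(sprintf("zero-size image: %s", path), call. = FALSE)
  }
  conform_gray(raw)
}

# Collapse an array read by png/tiff to a 2D luminance matrix.
to_luminance <- function(a) {
  if (is.matrix(a)) return(a)
  d <- dim(a)
  if (length(d) == 3L) {
    if (d[3] == 1L) return(a[, , 1])
    # channels 1:3 are RGB; a 4th (alpha) channel is ignored
    return(0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3])
  }
  stop("expected a 2D or 2D-multichannel image", call. = FALSE)
}

# Preserve values already on the 8-bit integer grid; otherwise min-max rescale.
conform_gray <- function(raw) {
  v <- as.vector(raw)
  if (anyNA(v) || !all(is.finite(v))) {
    stop("image contains missing or non-finite values", call. = FALSE)
  }
  on_grid <- all(abs(v - round(v)) < 1e-9) && min(v) >= 0 && max(v) <= 255
  if (on_grid) {
    out <- matrix(as.integer(round(v)), nrow(raw), ncol(raw))
  } else {
    out <- normalize_quantize(raw)
  }
  out
}

#' Normalize and quantize an intensity grid to 8-bit gray levels
#'
#' Rescales values to \[0, 1\] by `(x - min) / (max - min)` and quantizes to
#' `round(255 * x)` (half up). A constant grid maps to all zeros rather than
#' erroring, so degenerate fixtures stay usable.
#'
#' @param raw A numeric matrix (or vector) of intensities; at least one value.
#' @return An integer matrix (or vector) of gray levels in \[0, 255\].
#' @examples
#' normalize_quantize(matrix(c(50, 150), 1))  # -> 0, 255
#' @export
normalize_quantize <- function(raw) {
  if (length(raw) == 0L) stop("`raw` must have at least one pixel", call. = FALSE)
  v <- as.vector(raw)
  if (anyNA(v) || !all(is.finite(v))) {
    stop("`raw` contains missing or non-finite values", call. = FALSE)
  }
  rng <- range(v)
  if (rng[1] == rng[2]) {
    out <- rep(0L, length(v))
  } else {
    out <- as.integer(round_half_up(255 * (v - rng[1]) / (rng[2] - rng[1])))
  }
  if (is.matrix(raw)) out <- matrix(out, nrow(raw), ncol(raw))
  out
}

#' Write a gray or label image as 8-bit PNG or TIFF
#'
#' @param img Integer matrix with values in \[0, 255\] (gray image or label
#'   map with labels `0..K-1`).
#' @param path Output path ending in `.png`, `.tif`, or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  assert_gray_image(img)
  ext <- tolower(sub(".*\\.", "", path))
  m <- img / 255
  switch(ext,
    png = png::writePNG(m, path),
    tif = ,
    tiff = tiff::writeTIFF(m, path, bits.per.sample = 8L),
    stop(sprintf("unsupported output format: .%s", ext), call. = FALSE)
  )
  invisible(path)
}

#' Gray-level histogram of an image
#'
#' @param img Integer matrix of gray levels in \[0, 255\].
#' @return An object of class `gray_histogram`: a list with `counts`
#'   (256 nonnegative integers indexed by gray level 0..255) and `total`
#'   (pixel count). `tidy()` turns it into a tibble.
#' @export
gray_histogram <- function(img) {
  assert_gray_image(img)
  counts <- tabulate(as.vector(img) + 1L, nbins = 256L)
  structure(list(counts = counts, total = length(img)),
            class = "gray_histogram")
}

assert_histogram <- function(hist) {
  if (!inherits(hist, "gray_histogram")) {
    stop("`hist` must be a `gray_histogram` (see gray_histogram())", call. = FALSE)
  }
  if (hist$total <= 0L || sum(hist$counts) != hist$total) {
    stop("invalid histogram: counts must sum to a positive total", call. = FALSE)
  }
  invisible(hist)
}

#' @exportS3Method generics::tidy
tidy.gray_histogram <- function(x, ...) {
  tibble::tibble(level = 0:255, count = as.integer(x$counts))
}

#' @export
print.gray_histogram <- function(x, ...) {
  nz <- which(x$counts > 0L) - 1L
  cat(sprintf("<gray_histogram> %d pixels over %d occupied levels [%d, %d]\n",
              x$total, length(nz), min(nz), max(nz)))
  invisible(x)
}
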