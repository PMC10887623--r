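#' @useDynLib detrunc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif quantile fft mvfft
#' @importFrom utils modifyList
NULL

#' Construct a 2D attenuation image
#'
#' An `image_grid` is the package's Cartesian raster container: a numeric
#' matrix of attenuation values plus the physical pixel size and a nominal
#' display window. All images entering the polar transform must be square.
#'
#' @param pixels Numeric matrix (H x W) of finite attenuation values.
#' @param pixel_size Physical side length of one pixel (arbitrary units).
#' @param value_range Length-2 nominal display window `c(lo, hi)`.
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(pixels, pixel_size = 1, value_range = c(0, 1)) {
  pixels <- as.matrix(pixels)
  stopifnot(is.numeric(pixels), nrow(pixels) >= 16, ncol(pixels) >= 16)
  if (!all(is.finite(pixels))) stop("image contains non-finite values")
  stopifnot(length(value_range) == 2, pixel_size > 0)
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 value_range = as.numeric(value_range)),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid %dx%d, pixel %g, range [%.4g, %.4g]>\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.image_grid <- function(x) dim(x$pixels)

is_square <- function(img) nrow(img$pixels) == ncol(img$pixels)

#' Vectorised bilinear sampling of a matrix
#'
#' Samples `mat` at fractional (row, col) positions (1-based); positions
#' outside the matrix return `fill`.
#'
#' @param mat Numeric matrix.
#' @param row,col Numeric vectors of equal length with sample positions.
#' @param fill Value returned outside the matrix support.
#' @return Numeric vector of sampled values.
#' @keywords internal
bilinear_sample <- function(mat, row, col, fill = 0) {
  H <- nrow(mat); W <- ncol(mat)
  i0 <- floor(row); j0 <- floor(col)
  fi <- row - i0; fj <- col - j0
  v <- rep(fill, length(row))
  gather <- function(ii, jj) {
    ok <- ii >= 1 & ii <= H & jj >= 1 & jj <= W
    out <- numeric(length(ii))
    if (any(ok)) out[ok] <- mat[cbind(ii[ok], jj[ok])]
    out
  }
  inside <- i0 >= 0 & i0 <= H & j0 >= 0 & j0 <= W  # at least partly inside
  v <- (1 - fi) * (1 - fj) * gather(i0, j0) +
       (1 - fi) * fj       * gather(i0, j0 + 1) +
       fi       * (1 - fj) * gather(i0 + 1, j0) +
       fi       * fj       * gather(i0 + 1, j0 + 1)
  v[!inside] <- fill
  v
}

#' Resample an image onto a centred target grid
#'
#' Both grids are taken to be centred on the same physical origin. Used to put
#' a phantom onto the reconstruction grid so simulated pairs are pixel-aligned.
#'
#' @param img An `image_grid`.
#' @param out_size Target side length in pixels.
#' @param pixel_size Target physical pixel size.
#' @return An `image_grid` of side `out_size`.
#' @export
resample_to_grid <- function(img, out_size, pixel_size) {
  H <- nrow(img$pixels); W <- ncol(img$pixels)
  ctr <- (out_size + 1) / 2
  xy <- ((seq_len(out_size) - ctr)) * pixel_size
  X <- matrix(xy, out_size, out_size, byrow = TRUE)   # physical x per column
  Y <- matrix(xy, out_size, out_size)                 # physical y per row
  src_row <- Y / img$pixel_size + (H + 1) / 2
  src_col <- X / img$pixel_size + (W + 1) / 2
  vals <- bilinear_sample(img$pixels, as.vector(src_row), as.vector(src_col))
  image_grid(matrix(vals, out_size, out_size), pixel_size, img$value_range)
}

#' Mask of the inscribed circle of a square image
#'
#' @param n Side length in pixels.
#' @param frac Fraction of the inscribed radius to keep (default 1).
#' @return Logical n x n matrix, TRUE inside the disk.
#' @export
inscribed_mask <- function(n, frac = 1) {
  ctr <- (n + 1) / 2
  r <- (n - 1) / 2 * frac
  d <- outer(seq_len(n) - ctr, seq_len(n) - ctr,
             function(a, b) sqrt(a^2 + b^2))
  d <= r
}

#' Write / read an image as a plain TSV matrix with a JSON sidecar
#'
#' Lossless, diff-able storage: tab-separated values for the raster and a
#' `<path>.json` sidecar with pixel size and value range.
#'
#' @param img An `image_grid`.
#' @param path Output file path (`.tsv`).
#' @return `write_image` returns `path` invisibly; `read_image` the image.
#' @export
write_image <- function(img, path) {
  data.table::fwrite(data.table::as.data.table(img$pixels), path,
                     sep = "\t", col.names = FALSE)
  jsonlite::write_json(list(pixel_size = img$pixel_size,
                            value_range = img$value_range),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  m <- as.matrix(data.table::fread(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  image_grid(m, meta$pixel_size, meta$value_range)
}

#' Optional 16-bit PNG preview of an image
#'
#' Requires the `png` package; values are linearly windowed to `value_range`.
#'
#' @param img An `image_grid`.
#' @param path Output PNG path.
#' @export
write_preview_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    warning("png package not available; preview skipped")
    return(invisible(NULL))
  }
  lo <- img$value_range[1]; hi <- img$value_range[2]
  m <- pmin(pmax((img$pixels - lo) / (hi - lo), 0), 1)
  png::writePNG(m, path, dpi = NULL)
  invisible(path)
}
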