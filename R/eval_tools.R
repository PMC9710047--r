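# Contact-matrix comparison toolkit: difference-of-Gaussians band-pass
# transform, binary discretization, stripe-end matching scores, pixel
# accuracy around barriers, and per-diagonal correlation.
#
# All operations work on the "band image" of a matrix: a band_rows x nbins
# array whose element (k+1, i+1) is the matrix value at bin pair (i, i+k),
# i.e. row k holds the k-th off-diagonal. Cells whose second bin would fall
# beyond the chromosome (the matrix corner) are NA and are excluded from
# scoring.

#' Band image of a banded contact matrix
#'
#' @param mat A [banded_matrix()].
#' @return Numeric `band_rows x nbins` matrix; corner cells are `NA`.
#' @export
band_image <- function(mat) {
  stopifnot(inherits(mat, "banded_matrix"))
  img <- mat$counts * 1.0
  k <- matrix(0:(mat$band_rows - 1), mat$band_rows, mat$nbins)
  i <- matrix(0:(mat$nbins - 1), mat$band_rows, mat$nbins, byrow = TRUE)
  img[i + k >= mat$nbins] <- NA
  img
}

gaussian_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with symmetric-reflect padding at the band edges.
gaussian_blur <- function(x, sigma) {
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  conv_dim1 <- function(m) {
    n <- nrow(m)
    idx <- c(pmin(r:1, n), 1:n, pmax(n - seq_len(r) + 1L, 1L))
    p <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * p[(j - 1L) + 1:n, , drop = FALSE]
    out
  }
  t(conv_dim1(t(conv_dim1(x))))
}

#' Difference-of-Gaussians transform of a band image
#'
#' Blurs the band image at `sigma1` and at `sigma2` (pixels) and subtracts
#' the blurrier version, a band-pass filter that highlights stripes and dots.
#' `NA` corner cells are treated as 0 during convolution and restored to `NA`
#' afterwards; band edges use reflect padding.
#'
#' @param img Band image (see [band_image()]) or plain numeric matrix.
#' @param sigma1,sigma2 Gaussian widths in pixels; `sigma2 > sigma1 > 0`.
#' @return Real-valued matrix of the same shape.
#' @export
dog_transform <- function(img, sigma1 = 1.0, sigma2 = 1.6) {
  if (!(sigma2 > sigma1 && sigma1 > 0))
    stop("require sigma2 > sigma1 > 0, got sigma1 = ", sigma1,
         ", sigma2 = ", sigma2)
  nas <- is.na(img)
  x <- img
  x[nas] <- 0
  out <- gaussian_blur(x, sigma1) - gaussian_blur(x, sigma2)
  out[nas] <- NA
  out
}

#' Discretize a matrix with a step threshold
#'
#' Values `>= threshold` map to 1, values below to 0; `NA` stays `NA`.
#'
#' @param img Numeric matrix.
#' @param threshold Threshold (`-Inf` maps everything to 1).
#' @return Binary matrix.
#' @export
discretize <- function(img, threshold) {
  stopifnot(length(threshold) == 1, !is.na(threshold))
  out <- (img >= threshold) * 1
  out
}

#' End of a stripe in a pixel vector
#'
#' Given the vector of (binary) pixel values starting at the matrix diagonal
#' and extending away from it, the last non-zero pixel marks the end of a
#' loop-extrusion stripe.
#'
#' @param v Numeric vector; `NA` entries (outside the matrix) are ignored.
#' @return 0-based index of the last non-zero element, or `NA` if all zero.
#' @export
stripe_end <- function(v) {
  idx <- which(!is.na(v) & v != 0)
  if (length(idx) == 0L) return(NA_integer_)
  max(idx) - 1L
}

# Column-of-pixels view: element (k+1, j+1) is the matrix value at bin pair
# (j-k, j), i.e. the vector starting at diagonal bin j and extending up the
# j-th matrix column.
column_view <- function(img) {
  w <- nrow(img)
  n <- ncol(img)
  out <- matrix(NA_real_, w, n)
  for (k in 0:(w - 1)) {
    if (k + 1 <= n) out[k + 1, (k + 1):n] <- img[k + 1, 1:(n - k)]
  }
  out
}

#' Stripe-end match scores between two binary band images
#'
#' For every bin, the row of pixels (and, independently, the column of
#' pixels) starting at the diagonal is reduced to its stripe end
#' ([stripe_end()]); the per-bin score records whether reference and target
#' agree. Two empty vectors (no stripe in either) count as agreement.
#'
#' @param ref,target Binary band images of identical shape.
#' @param mode `"similarity"` (1 = match) or `"dissimilarity"`
#'   (1 = mismatch).
#' @return list with numeric per-bin vectors `rows` and `cols`.
#' @export
score_matrices <- function(ref, target, mode = c("similarity", "dissimilarity")) {
  mode <- match.arg(mode)
  if (!all(dim(ref) == dim(target)))
    stop("band images differ in shape: ", paste(dim(ref), collapse = "x"),
         " vs ", paste(dim(target), collapse = "x"))
  ends <- function(m) apply(m, 2, stripe_end)
  agree <- function(a, b) as.numeric((is.na(a) & is.na(b)) |
                                       (!is.na(a) & !is.na(b) & a == b))
  rows <- agree(ends(ref), ends(target))
  cols <- agree(ends(column_view(ref)), ends(column_view(target)))
  if (mode == "dissimilarity") {
    rows <- 1 - rows
    cols <- 1 - cols
  }
  list(rows = rows, cols = cols)
}

#' Pixel accuracy in subdiagonal windows around barriers
#'
#' Over the union of `window`-bp subdiagonal windows centered on the barrier
#' bins (pixels whose two bins both lie within `window/2` of a barrier),
#' the fraction of pixels classified identically in the two binary matrices.
#'
#' @param ref,target Binary band images of identical shape.
#' @param barrier_bins 0-based bin indices of the barriers (non-empty).
#' @param window Window size, bp.
#' @param bin_size Bin size, bp.
#' @return Fraction in \[0, 1\].
#' @export
pixel_accuracy <- function(ref, target, barrier_bins, window = 3e6,
                           bin_size = 5000) {
  if (length(barrier_bins) == 0) stop("barrier list is empty")
  if (!all(dim(ref) == dim(target))) stop("band images differ in shape")
  w <- nrow(ref)
  n <- ncol(ref)
  half <- floor(window / bin_size / 2)
  mask <- matrix(FALSE, w, n)
  kmat <- matrix(0:(w - 1), w, n)
  imat <- matrix(0:(n - 1), w, n, byrow = TRUE)
  for (b in barrier_bins) {
    mask <- mask | (imat >= b - half & imat + kmat <= b + half)
  }
  mask <- mask & !is.na(ref) & !is.na(target)
  if (!any(mask)) stop("no band pixels fall inside the barrier windows")
  mean(ref[mask] == target[mask])
}

#' Per-diagonal correlation of two matrices
#'
#' Pearson correlation of pixel values at each off-diagonal distance, from
#' the main diagonal up to the band width. Constant diagonals (zero variance
#' in either matrix) yield `NA`.
#'
#' @param ref,target Band images of identical shape.
#' @return Numeric vector of length `band_rows`; entry k is the correlation
#'   at bin distance k-1.
#' @export
diagonal_correlation <- function(ref, target) {
  if (!all(dim(ref) == dim(target))) stop("band images differ in shape")
  vapply(seq_len(nrow(ref)), function(k) {
    a <- ref[k, ]
    b <- target[k, ]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 2) return(NA_real_)
    if (sd(a[ok]) == 0 || sd(b[ok]) == 0) return(NA_real_)
    cor(a[ok], b[ok])
  }, numeric(1))
}

#' Transform a contact matrix for stripe scoring
#'
#' Convenience pipeline: band image -> difference of Gaussians ->
#' discretization, the `transform` step of the comparison workflow.
#'
#' @param mat A [banded_matrix()].
#' @param sigma1,sigma2 DoG widths (pixels).
#' @param threshold Discretization threshold.
#' @return Binary band image.
#' @export
transform_matrix <- function(mat, sigma1 = 1.0, sigma2 = 1.6, threshold = 0.75) {
  discretize(dog_transform(band_image(mat), sigma1, sigma2), threshold)
}
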