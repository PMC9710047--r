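# Banded symmetric contact-count matrix. Only pixels within a fixed genomic
# distance of the diagonal are stored: element (i, j) with i <= j and
# j - i < band_rows lives at row (j - i + 1), column (i + 1) of a dense
# band_rows x nbins integer matrix, so storage grows with nbins * band_rows,
# never with nbins^2.

#' Create an empty banded contact matrix
#'
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length, bp.
#' @param bin_size Bin size, bp.
#' @param diagonal_width Band width, bp: contacts at genomic distance
#'   `>= diagonal_width` are discarded (half-open band).
#' @return An object of class `banded_matrix`.
#' @export
banded_matrix <- function(chrom, chrom_length, bin_size, diagonal_width) {
  stopifnot(chrom_length >= 1, bin_size >= 1, diagonal_width >= bin_size)
  nbins <- as.integer(ceiling(chrom_length / bin_size))
  band_rows <- as.integer(min(ceiling(diagonal_width / bin_size), nbins))
  structure(
    list(
      chrom = as.character(chrom),
      chrom_length = as.numeric(chrom_length),
      bin_size = as.numeric(bin_size),
      nbins = nbins,
      band_rows = band_rows,
      counts = matrix(0L, nrow = band_rows, ncol = nbins),
      discards = 0
    ),
    class = "banded_matrix"
  )
}

#' @export
print.banded_matrix <- function(x, ...) {
  cat(sprintf(
    "<banded_matrix> %s: %d bins x %d band rows (bin %g bp), %g contacts, %g discarded\n",
    x$chrom, x$nbins, x$band_rows, x$bin_size, cm_total(x), x$discards))
  invisible(x)
}

#' Number of addressable pixels in the band
#'
#' Per chromosome: `nbins * band_rows` truncated at the matrix corner (pixels
#' whose second bin would fall beyond the chromosome are not addressable).
#'
#' @param chrom_length Chromosome length, bp.
#' @param bin_size Bin size, bp.
#' @param diagonal_width Band width, bp.
#' @return Pixel count (numeric, may exceed .Machine$integer.max).
#' @export
band_pixel_count <- function(chrom_length, bin_size, diagonal_width) {
  stopifnot(chrom_length > 0, bin_size > 0, diagonal_width > 0)
  nbins <- ceiling(chrom_length / bin_size)
  w <- min(ceiling(diagonal_width / bin_size), nbins)
  # row k (distance k bins, k = 0..w-1) has nbins - k pixels
  nbins * w - w * (w - 1) / 2
}

#' Increment a banded contact matrix at base-pair positions
#'
#' Increments the (min, max)-ordered bin pair for each (pos1, pos2); pairs at
#' genomic bin distance `>= band_rows` are dropped and counted in the discard
#' tally. Vectorized over positions.
#'
#' @param mat A `banded_matrix`.
#' @param pos1,pos2 Base-pair positions in `[0, chrom_length)`.
#' @param n Count(s) to add (recycled).
#' @return The updated matrix.
#' @export
cm_increment <- function(mat, pos1, pos2, n = 1L) {
  stopifnot(inherits(mat, "banded_matrix"), length(pos1) == length(pos2))
  if (any(pos1 < 0 | pos1 >= mat$chrom_length |
            pos2 < 0 | pos2 >= mat$chrom_length))
    stop("position outside chromosome [0, ", mat$chrom_length, ")")
  cm_increment_bins(mat,
                    floor(pos1 / mat$bin_size),
                    floor(pos2 / mat$bin_size),
                    n)
}

# Bin-level increment (0-based bin ids), shared by cm_increment and the
# engine aggregation path.
cm_increment_bins <- function(mat, bin1, bin2, n = 1L) {
  n <- rep_len(as.numeric(n), length(bin1))
  i <- pmin(bin1, bin2)
  j <- pmax(bin1, bin2)
  k <- j - i
  inband <- k < mat$band_rows
  mat$discards <- mat$discards + sum(n[!inband])
  if (any(inband)) {
    # column-major storage: element (row k+1, col i+1) at i * band_rows + k + 1
    idx <- i[inband] * mat$band_rows + k[inband] + 1
    add <- vapply(split(n[inband], idx), sum, numeric(1))
    at <- as.integer(names(add))
    mat$counts[at] <- mat$counts[at] + add
  }
  mat
}

#' Read a contact count
#'
#' Symmetric accessor: `cm_get(m, i, j) == cm_get(m, j, i)`; out-of-band
#' pairs read as 0.
#'
#' @param mat A `banded_matrix`.
#' @param bin1,bin2 0-based bin indices.
#' @return Count(s).
#' @export
cm_get <- function(mat, bin1, bin2) {
  stopifnot(all(bin1 >= 0 & bin1 < mat$nbins & bin2 >= 0 & bin2 < mat$nbins))
  i <- pmin(bin1, bin2)
  j <- pmax(bin1, bin2)
  k <- j - i
  out <- numeric(length(i))
  inband <- k < mat$band_rows
  out[inband] <- mat$counts[i[inband] * mat$band_rows + k[inband] + 1]
  out
}

#' Total stored contacts
#' @param mat A `banded_matrix`.
#' @return Sum of all in-band counts.
#' @export
cm_total <- function(mat) sum(mat$counts)

#' Mean contact density
#'
#' Total stored counts divided by the number of addressable band pixels; the
#' quantity the default stopping criterion (1 contact per pixel) is defined
#' on.
#'
#' @param mat A `banded_matrix`.
#' @return Contacts per pixel.
#' @export
mean_contact_density <- function(mat) {
  w <- mat$band_rows
  pixels <- mat$nbins * w - w * (w - 1) / 2
  cm_total(mat) / pixels
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Upper-triangle pixel table of a banded matrix
#'
#' @param mat A `banded_matrix`.
#' @return data.frame `bin1`, `bin2` (0-based, bin1 <= bin2), `count`, sorted
#'   by (bin1, bin2), non-zero pixels only.
#' @export
cm_pixels <- function(mat) {
  nz <- which(mat$counts != 0)
  if (length(nz) == 0L)
    return(data.frame(bin1 = integer(), bin2 = integer(), count = numeric()))
  k <- (nz - 1L) %% mat$band_rows
  i <- (nz - 1L) %/% mat$band_rows
  out <- data.frame(bin1 = i, bin2 = i + k, count = mat$counts[nz])
  out[order(out$bin1, out$bin2), , drop = FALSE]
}

# Rebuild a banded matrix from a pixel table (inverse of cm_pixels).
cm_from_pixels <- function(chrom, chrom_length, bin_size, diagonal_width,
                           pixels) {
  mat <- banded_matrix(chrom, chrom_length, bin_size, diagonal_width)
  if (nrow(pixels) > 0)
    mat <- cm_increment_bins(mat, pixels$bin1, pixels$bin2, pixels$count)
  mat
}

#' Densify a banded matrix
#'
#' Mainly for tests and small examples; the full `nbins x nbins` symmetric
#' matrix.
#'
#' @param x A `banded_matrix`.
#' @param ... Unused.
#' @return A dense numeric matrix.
#' @export
as.matrix.banded_matrix <- function(x, ...) {
  out <- matrix(0, x$nbins, x$nbins)
  px <- cm_pixels(x)
  if (nrow(px)) {
    out[cbind(px$bin1 + 1L, px$bin2 + 1L)] <- px$count
    out[cbind(px$bin2 + 1L, px$bin1 + 1L)] <- px$count
  }
  out
}
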