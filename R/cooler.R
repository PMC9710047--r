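# Single-resolution cooler (HDF5) read/write. The layout follows the cooler
# schema v3: /chroms, /bins, /pixels (upper-triangle, sorted by bin1_id then
# bin2_id, global bin ids), /indexes/{chrom_offset,bin1_offset}, plus the
# standard root attributes. Inter-chromosomal pixels never occur (the model
# is intra-chromosomal only).

#' Write banded contact matrices to a cooler file
#'
#' @param matrices Named list of [banded_matrix()] objects, one per
#'   chromosome, in chromosome order.
#' @param chroms data.frame with `name`, `length` (as from
#'   [load_chrom_sizes()]); names must match `names(matrices)`.
#' @param bin_size Bin size, bp; must equal every matrix's bin size.
#' @param path Output `.cool` path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_cooler <- function(matrices, chroms, bin_size, path) {
  stopifnot(is.list(matrices), nrow(chroms) == length(matrices))
  if (!identical(names(matrices), chroms$name))
    stop("matrix names must match chromosome names, in order")
  for (m in matrices) {
    if (!inherits(m, "banded_matrix")) stop("matrices must be banded_matrix objects")
    if (m$bin_size != bin_size)
      stop("mismatched bin sizes: matrix has ", m$bin_size, ", expected ", bin_size)
  }
  nbins_per_chrom <- vapply(matrices, function(m) m$nbins, integer(1))
  bin_offset <- c(0, cumsum(as.numeric(nbins_per_chrom)))

  # bins table
  bin_chrom <- integer(0); bin_start <- numeric(0); bin_end <- numeric(0)
  for (ci in seq_len(nrow(chroms))) {
    nb <- nbins_per_chrom[ci]
    st <- (seq_len(nb) - 1) * bin_size
    bin_chrom <- c(bin_chrom, rep.int(ci - 1L, nb))
    bin_start <- c(bin_start, st)
    bin_end <- c(bin_end, pmin(st + bin_size, chroms$length[ci]))
  }
  nbins <- length(bin_start)

  # pixels table (global ids)
  px <- vector("list", length(matrices))
  for (ci in seq_along(matrices)) {
    p <- cm_pixels(matrices[[ci]])
    if (nrow(p)) {
      p$bin1 <- p$bin1 + bin_offset[ci]
      p$bin2 <- p$bin2 + bin_offset[ci]
    }
    px[[ci]] <- p
  }
  px <- do.call(rbind, px)
  nnz <- nrow(px)

  # bin1_offset: CSR-style index over pixels
  if (nnz > 0) {
    per_bin <- tabulate(px$bin1 + 1L, nbins)
    bin1_offset <- c(0, cumsum(per_bin))
  } else {
    bin1_offset <- rep(0, nbins + 1)
  }

  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "chroms")
  rhdf5::h5createGroup(path, "bins")
  rhdf5::h5createGroup(path, "pixels")
  rhdf5::h5createGroup(path, "indexes")

  as_h5_int <- function(x) {
    # int32 where it fits (the cooler norm at this scale), double otherwise
    if (length(x) == 0 || max(x) <= .Machine$integer.max) as.integer(x) else as.numeric(x)
  }
  rhdf5::h5write(chroms$name, path, "chroms/name")
  rhdf5::h5write(as_h5_int(chroms$length), path, "chroms/length")
  rhdf5::h5write(as.integer(bin_chrom), path, "bins/chrom")
  rhdf5::h5write(as_h5_int(bin_start), path, "bins/start")
  rhdf5::h5write(as_h5_int(bin_end), path, "bins/end")
  rhdf5::h5write(as.integer(px$bin1), path, "pixels/bin1_id")
  rhdf5::h5write(as.integer(px$bin2), path, "pixels/bin2_id")
  counts <- px$count
  if (nnz > 0 && all(counts == floor(counts)) && max(counts) < .Machine$integer.max) {
    rhdf5::h5write(as.integer(counts), path, "pixels/count")
  } else {
    rhdf5::h5write(as.numeric(counts), path, "pixels/count")
  }
  rhdf5::h5write(as.numeric(bin_offset), path, "indexes/chrom_offset")
  rhdf5::h5write(as.numeric(bin1_offset), path, "indexes/bin1_offset")

  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute("HDF5::Cooler", fid, "format")
  rhdf5::h5writeAttribute(3L, fid, "format-version")
  rhdf5::h5writeAttribute(as.integer(bin_size), fid, "bin-size")
  rhdf5::h5writeAttribute("fixed", fid, "bin-type")
  rhdf5::h5writeAttribute(as.integer(nbins), fid, "nbins")
  rhdf5::h5writeAttribute(as.integer(nrow(chroms)), fid, "nchroms")
  rhdf5::h5writeAttribute(as.integer(nnz), fid, "nnz")
  rhdf5::h5writeAttribute("symmetric-upper", fid, "storage-mode")
  rhdf5::h5writeAttribute(paste0("extrusim-", as.character(utils::packageVersion("extrusim"))),
                          fid, "generated-by")
  # private attribute so read_cooler can rebuild bands exactly
  dw <- max(vapply(matrices, function(m) m$band_rows * m$bin_size, numeric(1)))
  rhdf5::h5writeAttribute(as.numeric(dw), fid, "extrusim-diagonal-width")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read a single-resolution cooler file into banded matrices
#'
#' @param path `.cool` path.
#' @param diagonal_width Band width (bp) for the reconstructed matrices. By
#'   default the width recorded at write time is used if present, otherwise
#'   the smallest width holding every pixel.
#' @return list with `chroms` (data.frame), `bin_size`, and `matrices`
#'   (named list of [banded_matrix()]).
#' @export
read_cooler <- function(path, diagonal_width = NULL) {
  if (!file.exists(path)) stop("cooler file not found: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  name <- as.character(rhdf5::h5read(path, "chroms/name"))
  length_ <- as.numeric(rhdf5::h5read(path, "chroms/length"))
  chroms <- data.frame(name = name, length = length_, stringsAsFactors = FALSE)
  attrs <- rhdf5::h5readAttributes(path, "/")
  bin_size <- as.numeric(attrs[["bin-size"]])
  if (is.null(diagonal_width)) {
    diagonal_width <- attrs[["extrusim-diagonal-width"]]
    if (!is.null(diagonal_width)) diagonal_width <- as.numeric(diagonal_width)
  }
  bin1 <- as.numeric(rhdf5::h5read(path, "pixels/bin1_id"))
  bin2 <- as.numeric(rhdf5::h5read(path, "pixels/bin2_id"))
  count <- as.numeric(rhdf5::h5read(path, "pixels/count"))
  chrom_offset <- as.numeric(rhdf5::h5read(path, "indexes/chrom_offset"))
  if (is.null(diagonal_width)) {
    diagonal_width <- if (length(bin1)) (max(bin2 - bin1) + 1) * bin_size else bin_size
  }
  matrices <- vector("list", nrow(chroms))
  names(matrices) <- chroms$name
  for (ci in seq_len(nrow(chroms))) {
    lo <- chrom_offset[ci]; hi <- chrom_offset[ci + 1]
    sel <- bin1 >= lo & bin1 < hi
    pixels <- data.frame(bin1 = bin1[sel] - lo, bin2 = bin2[sel] - lo,
                         count = count[sel])
    matrices[[ci]] <- cm_from_pixels(chroms$name[ci], chroms$length[ci],
                                     bin_size, diagonal_width, pixels)
  }
  list(chroms = chroms, bin_size = bin_size, matrices = matrices)
}
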