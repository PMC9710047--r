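# Genomic coordinate plumbing: chromosome sets, barrier annotations, and the
# simulation configuration object. Coordinates are 0-based, half-open
# throughout, matching BED and cooler conventions.

#' Load a chrom.sizes file
#'
#' Reads a two-column (name, length) whitespace-separated file describing the
#' genome regions to simulate.
#'
#' @param path Path to a chrom.sizes file.
#' @return A data.frame with columns `name` (character) and `length`
#'   (integer bp), in file order.
#' @export
load_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chrom.sizes file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty chrom.sizes file: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  out <- vector("list", length(lines))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != 2L)
      stop(sprintf("malformed chrom.sizes line %d: expected 2 fields, got %d",
                   i, length(f)))
    len <- suppressWarnings(as.numeric(f[2L]))
    if (is.na(len) || len != floor(len))
      stop(sprintf("malformed chrom.sizes line %d: length '%s' is not an integer",
                   i, f[2L]))
    if (len < 1)
      stop(sprintf("invalid chrom.sizes line %d: length must be >= 1, got %s",
                   i, f[2L]))
    out[[i]] <- data.frame(name = f[1L], length = len,
                           stringsAsFactors = FALSE)
  }
  chroms <- do.call(rbind, out)
  if (anyDuplicated(chroms$name))
    stop("duplicate chromosome name(s): ",
         paste(unique(chroms$name[duplicated(chroms$name)]), collapse = ", "))
  chroms
}

#' Write a chrom.sizes file
#'
#' @param chroms data.frame with `name` and `length` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(chroms, path) {
  stopifnot(all(c("name", "length") %in% names(chroms)))
  write.table(format(chroms[, c("name", "length")], scientific = FALSE,
                     trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Load an extrusion-barrier annotation from BED
#'
#' Barriers are read from a BED6 file. The strand column encodes the blocking
#' direction: a `+` barrier (motif on the forward strand) blocks
#' reverse-moving extrusion units; `-` blocks forward-moving units. The score
#' column carries the barrier occupancy. With `score_dialect = "fraction"`
#' (the default) the score is taken directly as an occupancy in \[0, 1\]; with
#' `"ucsc"` a 0-1000 score is divided by 1000. A score of `"."` (or a missing
#' score column entry) falls back to `default_occupancy`.
#'
#' The barrier position is the midpoint of the interval, rounded down.
#'
#' @param path BED file path.
#' @param default_occupancy Occupancy used where the score is ".". `NULL`
#'   means scores are required.
#' @param default_puu Unbound self-transition probability assigned to every
#'   barrier (per-barrier P_UU is not part of the BED dialect).
#' @param score_dialect `"fraction"` (score already in \[0,1\]) or `"ucsc"`
#'   (0-1000, divided by 1000).
#' @return data.frame with columns `chrom`, `pos` (bp, midpoint), `blocking`
#'   (`"reverse"` or `"forward"`), `occupancy`, `puu`, `start`, `end`, `name`,
#'   sorted by (chrom, pos).
#' @export
load_barriers <- function(path, default_occupancy = NULL, default_puu = 0.7,
                          score_dialect = c("fraction", "ucsc")) {
  score_dialect <- match.arg(score_dialect)
  if (!file.exists(path)) stop("barrier BED file not found: ", path)
  bed <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = "character", comment.char = "#")
  if (ncol(bed) < 6L)
    stop("barrier BED needs 6 columns (strand carries the blocking direction), got ",
         ncol(bed))
  names(bed)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  start <- as.numeric(bed$start)
  end <- as.numeric(bed$end)
  if (any(is.na(start) | is.na(end) | start < 0 | end <= start))
    stop("invalid BED intervals: require 0 <= start < end")
  if (!all(bed$strand %in% c("+", "-")))
    stop("barrier strand must be '+' or '-' (blocking direction is required; '.' is not allowed)")
  occ <- rep(NA_real_, nrow(bed))
  has_score <- bed$score != "." & nzchar(bed$score)
  raw <- suppressWarnings(as.numeric(bed$score[has_score]))
  if (any(is.na(raw))) stop("non-numeric barrier score(s)")
  occ[has_score] <- if (score_dialect == "ucsc") raw / 1000 else raw
  if (any(!has_score)) {
    if (is.null(default_occupancy))
      stop("barrier(s) without score but no default_occupancy given")
    occ[!has_score] <- default_occupancy
  }
  if (any(occ < 0 | occ > 1))
    stop("barrier occupancy outside [0, 1] after dialect resolution")
  out <- data.frame(
    chrom = bed$chrom,
    pos = floor((start + end) / 2),
    blocking = ifelse(bed$strand == "+", "reverse", "forward"),
    occupancy = occ,
    puu = default_puu,
    start = start,
    end = end,
    name = bed$name,
    stringsAsFactors = FALSE
  )
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Write barriers back to BED6
#'
#' Inverse of [load_barriers()] (fraction score dialect): occupancy goes in
#' the score column, blocking direction in the strand column.
#'
#' @param barriers Barrier data.frame as returned by [load_barriers()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_barriers <- function(barriers, path) {
  bed <- data.frame(
    chrom = barriers$chrom,
    start = if ("start" %in% names(barriers)) barriers$start else barriers$pos,
    end = if ("end" %in% names(barriers)) barriers$end else barriers$pos + 1,
    name = if ("name" %in% names(barriers)) barriers$name else ".",
    score = barriers$occupancy,
    strand = ifelse(barriers$blocking == "reverse", "+", "-")
  )
  write.table(format(bed, scientific = FALSE, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Number of LEFs instantiated on a chromosome
#'
#' LEF count scales with chromosome length at `lef_density` LEFs per Mbp,
#' rounded to the nearest integer with a minimum of one LEF.
#'
#' @param chrom_length Chromosome length in bp.
#' @param lef_density LEFs per Mbp (> 0).
#' @return Integer LEF count.
#' @export
n_lefs <- function(chrom_length, lef_density) {
  stopifnot(chrom_length >= 1, lef_density > 0)
  pmax(1, round(chrom_length * lef_density / 1e6))
}

#' Simulation configuration
#'
#' Bundles every tunable of the extrusion engine with validated defaults.
#' Exactly one of `target_contact_density` / `target_epochs` governs
#' termination; density (default 1 contact per band pixel) is used unless
#' `target_epochs` is given.
#'
#' @param bin_size Matrix bin size, bp.
#' @param diagonal_width Band width: maximum genomic separation at which
#'   contacts are recorded, bp.
#' @param lef_density LEFs per Mbp of simulated DNA.
#' @param processivity Mean total DNA (bp) extruded by a LEF over its
#'   chromatin-bound lifetime; sets the per-epoch release probability
#'   `2 * mean_stride / processivity`.
#' @param mean_stride Mean per-unit extrusion stride per epoch, bp. Defaults
#'   to `bin_size`.
#' @param stride_sd_fraction Stride standard deviation as a fraction of
#'   `mean_stride` (strides are normal, truncated at 0, rounded to bp).
#' @param hard_stall_multiplier Lifetime extension for LEFs whose two units
#'   are both stalled at a convergent Bound barrier pair (release probability
#'   divided by this factor).
#' @param ncells Number of independent simulation instances per chromosome.
#' @param target_contact_density Target mean contacts per band pixel,
#'   aggregated over cells.
#' @param target_epochs If non-NULL, stop each cell after this many
#'   contact-sampling epochs instead of using the density criterion.
#' @param contact_sampling_fraction Fraction of active LEFs sampled for
#'   contact registration each epoch.
#' @param tad_to_loop_ratio Mean number of intra-TAD contacts registered per
#'   loop contact (positions drawn uniformly inside the loop).
#' @param contact_mode `"all"`, `"loop-only"` or `"tad-only"`.
#' @param burn_in_window Epoch window used to assess loop-size stabilization.
#' @param burn_in_tolerance Relative change of the windowed mean loop size
#'   below which burn-in ends.
#' @param burn_in_max_epochs Hard cap on burn-in epochs.
#' @param max_epochs_per_cell Safety cap on contact-phase epochs per cell.
#' @param track_bin_size Bin size (bp) for occupancy tracks.
#' @param seed Master seed; per-task seeds are derived from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(bin_size = 5000,
                       diagonal_width = 3e6,
                       lef_density = 20,
                       processivity = 200e3,
                       mean_stride = NULL,
                       stride_sd_fraction = 0.05,
                       hard_stall_multiplier = 5,
                       ncells = 512,
                       target_contact_density = 1,
                       target_epochs = NULL,
                       contact_sampling_fraction = 0.025,
                       tad_to_loop_ratio = 1.0,
                       contact_mode = c("all", "loop-only", "tad-only"),
                       burn_in_window = 16,
                       burn_in_tolerance = 0.02,
                       burn_in_max_epochs = 5000,
                       max_epochs_per_cell = 100000,
                       track_bin_size = 1000,
                       seed = 0) {
  contact_mode <- match.arg(contact_mode)
  if (is.null(mean_stride)) mean_stride <- bin_size
  cfg <- list(
    bin_size = as.numeric(bin_size),
    diagonal_width = as.numeric(diagonal_width),
    lef_density = as.numeric(lef_density),
    processivity = as.numeric(processivity),
    mean_stride = as.numeric(mean_stride),
    stride_sd_fraction = as.numeric(stride_sd_fraction),
    hard_stall_multiplier = as.numeric(hard_stall_multiplier),
    ncells = as.integer(ncells),
    target_contact_density = as.numeric(target_contact_density),
    target_epochs = if (is.null(target_epochs)) NULL else as.numeric(target_epochs),
    contact_sampling_fraction = as.numeric(contact_sampling_fraction),
    tad_to_loop_ratio = as.numeric(tad_to_loop_ratio),
    contact_mode = contact_mode,
    burn_in_window = as.integer(burn_in_window),
    burn_in_tolerance = as.numeric(burn_in_tolerance),
    burn_in_max_epochs = as.integer(burn_in_max_epochs),
    max_epochs_per_cell = as.integer(max_epochs_per_cell),
    track_bin_size = as.numeric(track_bin_size),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$bin_size >= 1,
    cfg$diagonal_width >= cfg$bin_size,
    cfg$lef_density > 0,
    cfg$processivity > 0,
    cfg$mean_stride > 0,
    cfg$stride_sd_fraction >= 0,
    cfg$hard_stall_multiplier >= 1,
    cfg$ncells >= 1,
    cfg$contact_sampling_fraction > 0,
    cfg$contact_sampling_fraction <= 1,
    cfg$tad_to_loop_ratio >= 0,
    cfg$burn_in_window >= 1,
    cfg$burn_in_tolerance > 0
  )
  if (!is.null(cfg$target_epochs)) {
    stopifnot(cfg$target_epochs >= 1)
  } else {
    stopifnot(cfg$target_contact_density > 0)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-26s %s\n", nm, if (is.null(v)) "NULL" else format(v)))
  }
  invisible(x)
}

# Deterministic per-task seed: a pure function of (master seed, chromosome
# name, cell index), kept below 2^31 so it is a valid R integer seed.
task_seed <- function(master_seed, chrom_name, cell_index) {
  m <- 2147483647
  h <- as.numeric(master_seed) %% m
  for (code in utf8ToInt(as.character(chrom_name))) {
    h <- (h * 131 + code) %% m
  }
  h <- (h * 48271 + as.numeric(cell_index) * 7919 + 1) %% m
  as.integer(h)
}
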