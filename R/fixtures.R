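# Synthetic-data generators: toy genomes, convergent-barrier annotations,
# self-referential reference matrices, and golden binary-matrix pairs. All
# outputs are deterministic given the spec seed, so every module is testable
# without external downloads.

#' Specification of a toy loop-extrusion system
#'
#' Each chromosome carries `n_pairs` convergent barrier pairs laid out
#' evenly: the chromosome is divided into `n_pairs` segments and each
#' segment gets a `+` barrier at 25% and a `-` barrier at 75% of its length,
#' so loops stall between the pair (a TAD with a corner dot).
#'
#' @param lengths Named numeric vector of chromosome lengths (bp); names are
#'   chromosome names (default `chrT`, 5 Mbp).
#' @param n_pairs Convergent barrier pairs per chromosome.
#' @param occupancy,puu Barrier parameters written to the annotation.
#' @param seed Seed for everything derived from this spec.
#' @return list of class `toy_spec`.
#' @export
toy_spec <- function(lengths = c(chrT = 5e6), n_pairs = 4,
                     occupancy = 0.8, puu = 0.9, seed = 0) {
  if (is.null(names(lengths)))
    names(lengths) <- paste0("chrT", seq_along(lengths))
  stopifnot(all(lengths >= 1), n_pairs >= 0,
            occupancy >= 0, occupancy <= 1, puu >= 0, puu <= 1)
  structure(list(lengths = lengths, n_pairs = n_pairs,
                 occupancy = occupancy, puu = puu, seed = seed),
            class = "toy_spec")
}

#' Toy genome as a chrom.sizes data.frame (and optional file)
#'
#' @param spec A [toy_spec()].
#' @param path If non-NULL, also write a chrom.sizes file there.
#' @return Chromosome data.frame.
#' @export
make_toy_genome <- function(spec, path = NULL) {
  chroms <- data.frame(name = names(spec$lengths),
                       length = as.numeric(spec$lengths),
                       stringsAsFactors = FALSE)
  if (!is.null(path)) write_chrom_sizes(chroms, path)
  chroms
}

#' Toy convergent-barrier annotation (and optional BED file)
#'
#' @param spec A [toy_spec()].
#' @param path If non-NULL, also write a BED6 file there.
#' @return Barrier data.frame as from [load_barriers()].
#' @export
make_barrier_annotation <- function(spec, path = NULL) {
  rows <- list()
  for (cn in names(spec$lengths)) {
    L <- spec$lengths[[cn]]
    if (spec$n_pairs == 0) next
    seg <- L / spec$n_pairs
    for (i in seq_len(spec$n_pairs)) {
      left <- floor(seg * (i - 1) + 0.25 * seg)
      right <- floor(seg * (i - 1) + 0.75 * seg)
      if (left <= 0 || right >= L - 1)
        stop("barrier layout overlaps chromosome ends on ", cn)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cn,
        pos = c(left, right),
        blocking = c("reverse", "forward"),
        occupancy = spec$occupancy,
        puu = spec$puu,
        start = c(left, right),
        end = c(left + 1, right + 1),
        name = paste0(cn, "_pair", i, c("_L", "_R")),
        stringsAsFactors = FALSE
      )
    }
  }
  barriers <- do.call(rbind, rows)
  if (is.null(barriers))
    barriers <- data.frame(chrom = character(), pos = numeric(),
                           blocking = character(), occupancy = numeric(),
                           puu = numeric(), start = numeric(), end = numeric(),
                           name = character(), stringsAsFactors = FALSE)
  rownames(barriers) <- NULL
  if (!is.null(path)) write_barriers(barriers, path)
  barriers
}

#' Toy stripe annotation matching the convergent-barrier layout
#'
#' A `+` barrier anchors loops on its right (a horizontal stripe in the
#' upper triangle: fixed row, varying column), a `-` barrier anchors loops
#' on its left (vertical stripe). Each barrier contributes one stripe
#' interval of `2 * pad_bins + 1` bins centered on the barrier.
#'
#' @param spec A [toy_spec()].
#' @param bin_size Matrix bin size, bp.
#' @param pad_bins Half-width of each stripe interval, bins.
#' @return data.frame `chrom`, `start`, `end`, `orientation` (`"H"`/`"V"`).
#' @export
make_toy_stripes <- function(spec, bin_size = 5000, pad_bins = 5) {
  barriers <- make_barrier_annotation(spec)
  if (nrow(barriers) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), orientation = character()))
  data.frame(
    chrom = barriers$chrom,
    start = pmax(0, barriers$pos - pad_bins * bin_size),
    end = barriers$pos + (pad_bins + 1) * bin_size,
    orientation = ifelse(barriers$blocking == "reverse", "H", "V"),
    stringsAsFactors = FALSE
  )
}

#' Self-referential reference matrix
#'
#' Runs the engine at the spec's known parameters and (optionally) writes
#' the result as a cooler plus a JSON sidecar recording the generating
#' parameters -- the ground truth for optimizer recovery experiments.
#'
#' @param spec A [toy_spec()].
#' @param config A [sim_config()]; its seed is taken from the spec.
#' @param path If non-NULL, write `<path>` (cooler) and `<path>.json`
#'   (sidecar).
#' @return list with `chroms`, `barriers`, `matrices`, `config`.
#' @export
make_reference_matrix <- function(spec, config = sim_config(), path = NULL) {
  chroms <- make_toy_genome(spec)
  barriers <- make_barrier_annotation(spec)
  config$seed <- as.integer(spec$seed)
  sim <- run_simulation(chroms, barriers, config)
  if (!is.null(path)) {
    write_cooler(sim$matrices, chroms, config$bin_size, path)
    sidecar <- list(occupancy = spec$occupancy, puu = spec$puu,
                    n_pairs = spec$n_pairs, seed = spec$seed,
                    lengths = as.list(spec$lengths))
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         pretty = TRUE)
  }
  list(chroms = chroms, barriers = barriers, matrices = sim$matrices,
       config = config)
}

#' Golden binary band-image pairs with brute-force expected scores
#'
#' Small fixture pairs for the stripe-matching scorer. Expected per-bin
#' scores are computed here by direct enumeration (an independent loop over
#' rows/columns), not by the scorer under test.
#'
#' @param case `"identity"`, `"one-flip"` (one row's stripe end moved), or
#'   `"random"`.
#' @param nbins,band_rows Fixture dimensions.
#' @param seed Seed for the `"random"` case.
#' @return list with `ref`, `target` (binary band images) and
#'   `expected_rows`, `expected_cols` (per-bin dissimilarity 0/1).
#' @export
make_toy_binary_matrices <- function(case = c("identity", "one-flip", "random"),
                                     nbins = 50, band_rows = 20, seed = 0) {
  case <- match.arg(case)
  set.seed(seed)
  ref <- matrix(rbinom(band_rows * nbins, 1, 0.2), band_rows, nbins)
  corner <- outer(0:(band_rows - 1), 0:(nbins - 1), "+") >= nbins
  ref[corner] <- NA
  target <- ref
  if (case == "one-flip") {
    # clear column 1 of the band (bin 0's row vector) beyond the diagonal
    target[2:band_rows, 1] <- 0
    target[1, 1] <- 1
    ref[1, 1] <- 1
    ref[band_rows, 1] <- 1  # ref stripe for bin 0 ends at band_rows - 1
  } else if (case == "random") {
    target <- matrix(rbinom(band_rows * nbins, 1, 0.2), band_rows, nbins)
    target[corner] <- NA
  }

  last_nonzero <- function(v) {
    v <- v[!is.na(v)]
    e <- NA_integer_
    for (i in seq_along(v)) if (v[i] != 0) e <- i - 1L
    e
  }
  n <- nbins
  w <- band_rows
  exp_rows <- numeric(n)
  exp_cols <- numeric(n)
  for (j in 0:(n - 1)) {
    # row vector of bin j: pairs (j, j+k)
    rr <- sapply(0:(w - 1), function(k) if (j + k < n) ref[k + 1, j + 1] else NA)
    rt <- sapply(0:(w - 1), function(k) if (j + k < n) target[k + 1, j + 1] else NA)
    er <- last_nonzero(rr)
    et <- last_nonzero(rt)
    exp_rows[j + 1] <- as.numeric(!((is.na(er) && is.na(et)) ||
                                      (!is.na(er) && !is.na(et) && er == et)))
    # column vector of bin j: pairs (j-k, j)
    cr <- sapply(0:(w - 1), function(k) if (j - k >= 0) ref[k + 1, j - k + 1] else NA)
    ct <- sapply(0:(w - 1), function(k) if (j - k >= 0) target[k + 1, j - k + 1] else NA)
    ec <- last_nonzero(cr)
    ecx <- last_nonzero(ct)
    exp_cols[j + 1] <- as.numeric(!((is.na(ec) && is.na(ecx)) ||
                                      (!is.na(ec) && !is.na(ecx) && ec == ecx)))
  }
  list(ref = ref, target = target,
       expected_rows = exp_rows, expected_cols = exp_cols)
}
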