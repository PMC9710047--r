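# The stochastic simulation driver: task scheduling over cells x
# chromosomes, burn-in, and the 9-step epoch loop producing contacts and
# occupancy tracks. The per-epoch core lives in compiled code
# (src/engine.cpp); this file owns task scheduling, seeding, aggregation,
# and R-level wrappers for the engine's primitive operations.

#' Bind inactive LEFs at uniformly drawn positions
#'
#' Each newly activated LEF places both of its extrusion units at the same
#' position, drawn uniformly on the chromosome, so a fresh loop has size 0.
#'
#' @param n Number of LEFs to activate.
#' @param chrom_length Chromosome length, bp.
#' @return data.frame with `rev` and `fwd` unit positions (bp).
#' @export
bind_lefs <- function(n, chrom_length) {
  stopifnot(chrom_length >= 1)
  if (n == 0) return(data.frame(rev = numeric(), fwd = numeric()))
  p <- pmin(floor(runif(n) * chrom_length), chrom_length - 1)
  data.frame(rev = p, fwd = p)
}

#' Index extrusion units in genomic order
#'
#' Returns the permutations that visit reverse units and forward units in
#' 5'->3' order. Stable for ties.
#'
#' @param lefs data.frame with `rev` and `fwd` positions of active LEFs.
#' @return list with integer orderings `rev_order` and `fwd_order`.
#' @export
index_units <- function(lefs) {
  list(rev_order = order(lefs$rev),
       fwd_order = order(lefs$fwd))
}

#' Generate candidate moves for extrusion units
#'
#' Strides are drawn from a normal distribution with mean `mean_stride` and
#' standard deviation `stride_sd_fraction * mean_stride`, truncated at 0 and
#' rounded to integer bp. The caller applies direction and boundary clipping
#' (reverse units move toward 0, forward units toward the chromosome end;
#' chromosome ends act as permanent barriers).
#'
#' @param n_units Number of strides to draw.
#' @param mean_stride Mean stride, bp.
#' @param stride_sd_fraction SD as a fraction of the mean.
#' @return Integer-valued numeric vector of strides (bp).
#' @export
generate_moves <- function(n_units, mean_stride, stride_sd_fraction = 0.05) {
  stopifnot(mean_stride > 0, stride_sd_fraction >= 0)
  pmax(round(rnorm(n_units, mean_stride, stride_sd_fraction * mean_stride)), 0)
}

#' Detect and resolve collision events for one epoch
#'
#' Applies, simultaneously, the three collision constraints of the model:
#' a unit stops 1 bp before a Bound barrier blocking its direction
#' (barrier stall); units of different LEFs may not pass one another --
#' two approaching units split the remaining gap (odd gap: the spare bp goes
#' to the unit ranked first in genomic order) and a unit blocked by an
#' already-stalled unit stalls behind it (LEF-LEF stall); and the two units
#' of one LEF never cross. Chromosome ends clip moves without setting a
#' stall.
#'
#' @param lefs data.frame of active LEFs with `rev` and `fwd` positions (bp).
#' @param rev_strides,fwd_strides Non-negative strides per LEF (bp).
#' @param barriers data.frame with `pos`, `blocking` (`"reverse"`/
#'   `"forward"`) and logical `bound`; may have zero rows.
#' @param chrom_length Chromosome length, bp.
#' @return list with updated `rev`/`fwd` positions and `rev_stall`/
#'   `fwd_stall` codes (`"none"`, `"barrier"`, `"lef-lef"`).
#' @export
detect_and_resolve_collisions <- function(lefs, rev_strides, fwd_strides,
                                          barriers, chrom_length) {
  stopifnot(nrow(lefs) == length(rev_strides),
            nrow(lefs) == length(fwd_strides))
  barriers <- barriers[order(barriers$pos), , drop = FALSE]
  res <- resolve_collisions_cpp(
    as.numeric(lefs$rev), as.numeric(lefs$fwd),
    as.numeric(rev_strides), as.numeric(fwd_strides),
    as.numeric(barriers$pos),
    as.integer(barriers$blocking == "forward"),
    as.logical(barriers$bound),
    as.numeric(chrom_length)
  )
  codes <- c("none", "barrier", "lef-lef")
  list(rev = res$rev_pos, fwd = res$fwd_pos,
       rev_stall = codes[res$rev_stall + 1L],
       fwd_stall = codes[res$fwd_stall + 1L])
}

#' Release probability and Bernoulli release of LEFs
#'
#' The base per-epoch release probability is `2 * mean_stride /
#' processivity` (both units extrude `mean_stride` bp per epoch on average,
#' and a LEF's lifetime should extrude `processivity` bp in total). LEFs
#' hard-stalled at a convergent Bound barrier pair (both units
#' barrier-stalled) are released with that probability divided by
#' `hard_stall_multiplier`.
#'
#' @param hard_stalled Logical vector, one entry per active LEF.
#' @param mean_stride,processivity,hard_stall_multiplier See [sim_config()].
#' @return Logical vector: `TRUE` for released LEFs.
#' @export
release_lefs <- function(hard_stalled, mean_stride, processivity,
                         hard_stall_multiplier = 1) {
  stopifnot(processivity > 0, hard_stall_multiplier >= 1)
  p <- 2 * mean_stride / processivity
  if (p > 1) {
    warning("release probability ", signif(p, 3), " clamped to 1")
    p <- 1
  }
  pe <- ifelse(hard_stalled, p / hard_stall_multiplier, p)
  runif(length(hard_stalled)) < pe
}

#' Task table for a simulation run
#'
#' One task per (chromosome, cell); the task seed is a pure function of the
#' master seed, the chromosome name and the cell index, so results do not
#' depend on the order in which tasks are executed.
#'
#' @param chroms Chromosome data.frame.
#' @param config A [sim_config()].
#' @return data.frame with `chrom`, `cell`, `seed`.
#' @export
make_tasks <- function(chroms, config) {
  out <- expand.grid(cell = seq_len(config$ncells), chrom = chroms$name,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$seed <- mapply(task_seed, config$seed, out$chrom, out$cell)
  out[, c("chrom", "cell", "seed")]
}

# Validate barriers, fill transition probabilities, apply deletions.
prepare_barriers <- function(barriers, chroms, deleted_regions = NULL,
                             clamp = FALSE) {
  if (is.null(barriers) || nrow(barriers) == 0) {
    return(data.frame(chrom = character(), pos = numeric(),
                      blocking = character(), occupancy = numeric(),
                      puu = numeric(), pbb = numeric()))
  }
  bad <- setdiff(unique(barriers$chrom), chroms$name)
  if (length(bad))
    stop("barrier chromosome(s) not in genome: ", paste(bad, collapse = ", "))
  b <- barriers
  if (!is.null(deleted_regions) && nrow(deleted_regions) > 0) {
    bs <- if ("start" %in% names(b)) b$start else b$pos
    be <- if ("end" %in% names(b)) b$end else b$pos + 1
    hit <- rep(FALSE, nrow(b))
    for (r in seq_len(nrow(deleted_regions))) {
      hit <- hit | (b$chrom == deleted_regions$chrom[r] &
                      bs < deleted_regions$end[r] &
                      be > deleted_regions$start[r])
    }
    b$occupancy[hit] <- 0
  }
  b$pbb <- occupancy_to_pbb(b$occupancy, b$puu, clamp = clamp)
  b
}

#' Run a loop-extrusion simulation
#'
#' Simulates `config$ncells` independent instances per chromosome and
#' aggregates their contacts into one banded matrix per chromosome. Each
#' cell contributes `target_contact_density / ncells` contacts per band
#' pixel (or runs for `target_epochs` epochs when that criterion governs).
#'
#' @param chroms Chromosome data.frame (see [load_chrom_sizes()]).
#' @param barriers Barrier data.frame (see [load_barriers()]); `NULL` or
#'   empty for a barrier-free run.
#' @param config A [sim_config()].
#' @param record_tracks If `TRUE`, record per-bin extrusion-unit visit
#'   counts (LEF occupancy profile).
#' @param deleted_regions Optional data.frame `chrom`, `start`, `end`:
#'   barriers overlapping these regions get occupancy 0 (in-silico border
#'   deletion).
#' @param collect_lifetimes If `TRUE`, collect the lifetime (in epochs) of
#'   every released LEF.
#' @param task_order Optional permutation of task rows (testing hook for the
#'   scheduling-independence contract).
#' @param clamp_infeasible If `TRUE`, infeasible (occupancy, P_UU) pairs get
#'   `P_BB = 0` instead of raising an error (used by the genetic optimizer,
#'   whose genotypes roam the full unit square).
#' @return list with `matrices` (named list of [banded_matrix()]), `report`
#'   (totals per chromosome and overall), `tracks` (per-chromosome visit
#'   vectors or NULL), `lifetimes`.
#' @export
run_simulation <- function(chroms, barriers = NULL, config = sim_config(),
                           record_tracks = FALSE, deleted_regions = NULL,
                           collect_lifetimes = FALSE, task_order = NULL,
                           clamp_infeasible = FALSE) {
  if (is.null(chroms) || nrow(chroms) == 0) stop("no chromosomes to simulate")
  barriers <- prepare_barriers(barriers, chroms, deleted_regions,
                               clamp = clamp_infeasible)

  matrices <- lapply(seq_len(nrow(chroms)), function(ci)
    banded_matrix(chroms$name[ci], chroms$length[ci], config$bin_size,
                  config$diagonal_width))
  names(matrices) <- chroms$name

  tasks <- make_tasks(chroms, config)
  if (!is.null(task_order)) tasks <- tasks[task_order, , drop = FALSE]

  density_governed <- is.null(config$target_epochs)
  per_cell_target <- vapply(chroms$name, function(cn) {
    if (!density_governed) return(-1)
    len <- chroms$length[chroms$name == cn]
    pixels <- band_pixel_count(len, config$bin_size, config$diagonal_width)
    ceiling(pixels * config$target_contact_density / config$ncells)
  }, numeric(1))
  max_epochs <- if (density_governed) config$max_epochs_per_cell
                else as.integer(config$target_epochs)

  tracks <- if (record_tracks) {
    setNames(lapply(chroms$length, function(len)
      numeric(ceiling(len / config$track_bin_size))), chroms$name)
  } else NULL
  lifetimes <- list()
  epochs <- setNames(numeric(nrow(chroms)), chroms$name)
  burnins <- setNames(numeric(nrow(chroms)), chroms$name)

  for (ti in seq_len(nrow(tasks))) {
    cn <- tasks$chrom[ti]
    len <- chroms$length[chroms$name == cn]
    bb <- barriers[barriers$chrom == cn, , drop = FALSE]
    bb <- bb[order(bb$pos), , drop = FALSE]
    par <- list(
      bin_size = config$bin_size,
      band_rows = matrices[[cn]]$band_rows,
      mean_stride = config$mean_stride,
      stride_sd = config$stride_sd_fraction * config$mean_stride,
      p_release = min(1, 2 * config$mean_stride / config$processivity),
      hard_mult = config$hard_stall_multiplier,
      sampling_fraction = config$contact_sampling_fraction,
      tad_ratio = config$tad_to_loop_ratio,
      contact_mode = match(config$contact_mode,
                           c("all", "loop-only", "tad-only")) - 1L,
      target_contacts = per_cell_target[[cn]],
      max_epochs = max_epochs,
      burn_in_window = config$burn_in_window,
      burn_in_tol = config$burn_in_tolerance,
      burn_in_max = config$burn_in_max_epochs,
      track_bin = if (record_tracks) config$track_bin_size else 0,
      collect_lifetimes = collect_lifetimes
    )
    set.seed(tasks$seed[ti])
    res <- simulate_cell_cpp(len, n_lefs(len, config$lef_density),
                             as.numeric(bb$pos),
                             as.integer(bb$blocking == "forward"),
                             as.numeric(bb$occupancy), as.numeric(bb$puu),
                             as.numeric(bb$pbb), par)
    if (length(res$bin1))
      matrices[[cn]] <- cm_increment_bins(matrices[[cn]], res$bin1, res$bin2)
    matrices[[cn]]$discards <- matrices[[cn]]$discards + res$discards
    if (record_tracks) tracks[[cn]] <- tracks[[cn]] + res$track
    if (collect_lifetimes) lifetimes[[length(lifetimes) + 1L]] <- res$lifetimes
    epochs[cn] <- epochs[cn] + res$epochs
    burnins[cn] <- burnins[cn] + res$burnin_epochs
  }

  totals <- vapply(matrices, cm_total, numeric(1))
  report <- list(
    contacts_per_chrom = totals,
    total_contacts = sum(totals),
    discards = sum(vapply(matrices, function(m) m$discards, numeric(1))),
    mean_density = vapply(matrices, mean_contact_density, numeric(1)),
    epochs_per_chrom = epochs,
    burnin_epochs_per_chrom = burnins,
    ntasks = nrow(tasks),
    config = config
  )
  list(matrices = matrices, report = report, tracks = tracks,
       lifetimes = if (collect_lifetimes) unlist(lifetimes) else NULL)
}

#' LEF occupancy profile from a simulation run
#'
#' Converts the per-bin extrusion-unit visit counts recorded by
#' [run_simulation()] (with `record_tracks = TRUE`) into a bedGraph-style
#' table. Raw counts sum to the total number of recorded unit visits;
#' `normalize = TRUE` divides by (cells x contact-phase epochs) to give a
#' time-and-cell-averaged occupancy.
#'
#' @param result A [run_simulation()] result.
#' @param chroms Chromosome data.frame used for the run.
#' @param normalize Divide counts by cells x epochs.
#' @return data.frame `chrom`, `start`, `end`, `value`.
#' @export
lef_occupancy_track <- function(result, chroms, normalize = FALSE) {
  if (is.null(result$tracks))
    stop("run_simulation() was called without record_tracks = TRUE")
  cfg <- result$report$config
  out <- lapply(chroms$name, function(cn) {
    v <- result$tracks[[cn]]
    if (normalize) {
      denom <- result$report$epochs_per_chrom[cn] -
        result$report$burnin_epochs_per_chrom[cn]
      v <- v / max(denom, 1)
    }
    st <- (seq_along(v) - 1) * cfg$track_bin_size
    data.frame(chrom = cn, start = st,
               end = pmin(st + cfg$track_bin_size,
                          chroms$length[chroms$name == cn]),
               value = v, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
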