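# Two-state (Bound/Unbound) Markov model of extrusion barriers.
#
# The chain is parameterized by the self-transition probabilities P_UU
# (Unbound -> Unbound) and P_BB (Bound -> Bound). Its stationary Bound
# probability -- the barrier occupancy pi_B -- is
#   pi_B = (1 - P_UU) / ((1 - P_UU) + (1 - P_BB)),
# so a user-facing (pi_B, P_UU) pair determines P_BB in closed form.

#' Bound self-transition probability from occupancy and unbound stability
#'
#' Solves the stationary-distribution relation for `P_BB`:
#' `P_BB = 1 - (1 - P_UU) * (1 - pi_B) / pi_B`. A pair is infeasible when
#' this is negative, i.e. when `pi_B < (1 - P_UU) / (2 - P_UU)`.
#'
#' @param occupancy Target stationary Bound probability `pi_B` in \[0, 1\].
#'   The limits are handled explicitly: `pi_B = 0` returns `P_BB = 0` (the
#'   chain is never Bound, so `P_BB` is irrelevant); `pi_B = 1` returns 1.
#' @param puu Unbound self-transition probability in \[0, 1).
#' @param clamp If `TRUE`, infeasible pairs are clamped to `P_BB = 0` (the
#'   realized occupancy is then the largest attainable for that `puu`)
#'   instead of raising an error. Used by the genetic optimizer, whose random
#'   genotypes may propose infeasible pairs.
#' @return `P_BB`, vectorized over inputs.
#' @export
occupancy_to_pbb <- function(occupancy, puu, clamp = FALSE) {
  stopifnot(all(occupancy >= 0 & occupancy <= 1), all(puu >= 0 & puu <= 1))
  out <- numeric(length(occupancy))
  puu <- rep_len(puu, length(occupancy))
  zero <- occupancy == 0
  one <- occupancy == 1
  mid <- !zero & !one
  out[zero] <- 0
  out[one] <- 1
  pbb <- 1 - (1 - puu[mid]) * (1 - occupancy[mid]) / occupancy[mid]
  if (any(pbb < 0)) {
    if (!clamp) {
      bad <- which(mid)[pbb < 0][1]
      feas <- (1 - puu[bad]) / (2 - puu[bad])
      stop(sprintf(
        "infeasible (occupancy, P_UU) pair: occupancy %.4g with P_UU %.4g requires occupancy >= %.4g",
        occupancy[bad], puu[bad], feas))
    }
    pbb <- pmax(pbb, 0)
  }
  out[mid] <- pbb
  out
}

#' Stationary Bound probability of the barrier chain
#'
#' @param puu Unbound self-transition probability.
#' @param pbb Bound self-transition probability.
#' @return `pi_B = (1 - P_UU) / ((1 - P_UU) + (1 - P_BB))`, vectorized.
#' @export
stationary_occupancy <- function(puu, pbb) {
  stopifnot(all(puu >= 0 & puu <= 1), all(pbb >= 0 & pbb <= 1))
  if (any(puu == 1 & pbb == 1))
    stop("P_UU = P_BB = 1: stationary distribution undefined")
  (1 - puu) / ((1 - puu) + (1 - pbb))
}

#' Draw initial barrier states
#'
#' One Bernoulli draw per barrier: Bound with probability equal to its
#' occupancy.
#'
#' @param occupancy Vector of occupancies.
#' @return Logical vector, `TRUE` = Bound.
#' @export
init_barrier_state <- function(occupancy) {
  stopifnot(all(occupancy >= 0 & occupancy <= 1))
  runif(length(occupancy)) < occupancy
}

#' Advance barrier states one epoch
#'
#' Each barrier transitions independently: from Unbound it stays Unbound with
#' probability `P_UU`, from Bound it stays Bound with probability `P_BB`.
#' Barriers with occupancy 0 are forced Unbound regardless of draws.
#'
#' @param state Logical vector of current states (`TRUE` = Bound).
#' @param puu,pbb Self-transition probabilities (recycled).
#' @param occupancy Occupancies, used only to pin zero-occupancy barriers to
#'   Unbound (default: none pinned).
#' @return Updated logical state vector.
#' @export
step_barrier_states <- function(state, puu, pbb, occupancy = NULL) {
  n <- length(state)
  puu <- rep_len(puu, n)
  pbb <- rep_len(pbb, n)
  u <- runif(n)
  new_state <- ifelse(state, u < pbb, u >= puu)
  if (!is.null(occupancy)) new_state[occupancy == 0] <- FALSE
  new_state
}

#' Map a ChIP-seq signal to barrier occupancies
#'
#' Bins a non-negative fold-change-over-control signal at `bin_size` (1 kbp
#' by default), then passes the per-bin mean signal through a logistic
#' function: `occupancy(x) = max_occupancy / (1 + exp(-steepness * (x -
#' midpoint)))`.
#'
#' @param track data.frame with columns `chrom`, `start`, `end`, `value`
#'   (bedGraph-style, 0-based half-open intervals).
#' @param midpoint Fold-change at which occupancy reaches half its maximum.
#' @param steepness Logistic slope (per fold-change unit).
#' @param max_occupancy Upper bound of the mapped occupancy.
#' @param bin_size Output bin size, bp.
#' @return data.frame `chrom`, `start`, `end`, `occupancy` per bin covered by
#'   the input track.
#' @export
occupancy_from_chipseq <- function(track, midpoint = 1.0, steepness = 2.0,
                                   max_occupancy = 0.9, bin_size = 1000) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(track)))
  if (any(track$value < 0)) stop("negative ChIP-seq signal value(s)")
  out <- lapply(split(track, track$chrom), function(tr) {
    lo <- floor(min(tr$start) / bin_size) * bin_size
    hi <- ceiling(max(tr$end) / bin_size) * bin_size
    starts <- seq(lo, hi - bin_size, by = bin_size)
    num <- numeric(length(starts))
    den <- numeric(length(starts))
    # mean signal per bin, weighting each interval by its overlap with the bin
    for (r in seq_len(nrow(tr))) {
      b0 <- floor(tr$start[r] / bin_size)
      b1 <- ceiling(tr$end[r] / bin_size) - 1
      for (b in b0:b1) {
        ov <- min(tr$end[r], (b + 1) * bin_size) - max(tr$start[r], b * bin_size)
        j <- b - lo / bin_size + 1
        num[j] <- num[j] + ov * tr$value[r]
        den[j] <- den[j] + ov
      }
    }
    covered <- den > 0
    x <- num[covered] / den[covered]
    data.frame(
      chrom = tr$chrom[1],
      start = starts[covered],
      end = starts[covered] + bin_size,
      occupancy = max_occupancy / (1 + exp(-steepness * (x - midpoint))),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Re-express barrier occupancy at a reference unbound stability
#'
#' Maps each barrier's `(pi_B, P_UU)` to the occupancy an equivalent barrier
#' with `P_UU = reference_puu` and the same `P_BB` would have. Used to make
#' occupancy profiles comparable across barriers with heterogeneous `P_UU`
#' (e.g., after per-barrier optimization).
#'
#' @param occupancy,puu Barrier parameters (vectorized).
#' @param reference_puu The common `P_UU` to normalize to.
#' @return Normalized occupancies.
#' @export
normalize_occupancy <- function(occupancy, puu, reference_puu = 0.7) {
  pbb <- occupancy_to_pbb(occupancy, puu)
  out <- numeric(length(pbb))
  zero <- occupancy == 0
  out[!zero] <- stationary_occupancy(reference_puu, pbb[!zero])
  out[zero] <- 0
  out
}

#' Barrier occupancy profile as a binned track
#'
#' Bins barrier occupancies (optionally re-expressed at a reference `P_UU`
#' via [normalize_occupancy()]) at `bin_size`; bins holding several barriers
#' take the maximum.
#'
#' @param barriers Barrier data.frame (see [load_barriers()]).
#' @param chroms Chromosome data.frame.
#' @param reference_puu If non-NULL, normalize occupancies to this `P_UU`.
#' @param bin_size Track bin size, bp.
#' @return data.frame `chrom`, `start`, `end`, `value` (bedGraph-style),
#'   non-empty bins only.
#' @export
barrier_occupancy_track <- function(barriers, chroms, reference_puu = NULL,
                                    bin_size = 1000) {
  occ <- barriers$occupancy
  if (!is.null(reference_puu))
    occ <- normalize_occupancy(occ, barriers$puu, reference_puu)
  bin <- floor(barriers$pos / bin_size)
  key <- paste(barriers$chrom, bin)
  agg <- tapply(occ, key, max)
  parts <- strsplit(names(agg), " ")
  out <- data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    start = as.numeric(vapply(parts, `[`, "", 2L)) * bin_size,
    value = as.numeric(agg),
    stringsAsFactors = FALSE
  )
  out$end <- out$start + bin_size
  out <- out[order(out$chrom, out$start), c("chrom", "start", "end", "value")]
  rownames(out) <- NULL
  out
}
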