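# Test helpers: a 1-bp micro-stepping collision oracle (independent of the
# package's analytical resolver), small simulation configs, and random
# instance generators.

# Brute-force collision oracle. Every tick, each unit with remaining stride
# attempts a 1-bp move in its direction, processed in genomic order. A unit
# stops permanently 1 bp before a Bound blocking barrier; a unit whose next
# bp is occupied by a different LEF's unit waits if that unit may still move
# and stalls behind it otherwise. When a tick passes with no movement,
# remaining movers adjacent to a foreign unit are mutually stalled.
# Positions must be distinct across units at entry.
micro_step_oracle <- function(rev, fwd, rev_stride, fwd_stride, barriers, L) {
  n <- length(rev)
  units <- data.frame(
    lef = rep(seq_len(n), 2),
    dir = rep(c(-1, 1), each = n),
    pos = c(rev, fwd),
    rem = c(rev_stride, fwd_stride),
    stall = rep("none", 2 * n),
    stringsAsFactors = FALSE
  )
  bound <- barriers[barriers$bound, , drop = FALSE]
  barrier_blocks <- function(p, dir) {
    nrow(bound) > 0 && any(
      bound$pos == p & ((dir == -1 & bound$blocking == "reverse") |
                          (dir == 1 & bound$blocking == "forward")))
  }
  repeat {
    moved <- FALSE
    for (u in order(units$pos, units$dir, units$lef)) {
      if (units$rem[u] <= 0 || units$stall[u] != "none") next
      np <- units$pos[u] + units$dir[u]
      if (np < 0 || np > L - 1) {
        units$rem[u] <- 0
        next
      }
      if (barrier_blocks(np, units$dir[u])) {
        units$stall[u] <- "barrier"
        units$rem[u] <- 0
        next
      }
      occ <- which(units$pos == np & units$lef != units$lef[u])
      if (length(occ) > 0) {
        if (all(units$rem[occ] <= 0 | units$stall[occ] != "none")) {
          units$stall[u] <- "lef-lef"
          units$rem[u] <- 0
        }
        next
      }
      units$pos[u] <- np
      units$rem[u] <- units$rem[u] - 1
      moved <- TRUE
    }
    if (!moved) {
      for (u in seq_len(nrow(units))) {
        if (units$rem[u] > 0 && units$stall[u] == "none") {
          np <- units$pos[u] + units$dir[u]
          if (np >= 0 && np <= L - 1 &&
              any(units$pos == np & units$lef != units$lef[u]))
            units$stall[u] <- "lef-lef"
        }
      }
      break
    }
  }
  list(rev = units$pos[units$dir == -1],
       fwd = units$pos[units$dir == 1],
       rev_stall = units$stall[units$dir == -1],
       fwd_stall = units$stall[units$dir == 1])
}

# Random small collision instance with distinct unit positions.
random_collision_instance <- function(n_lefs = 8, n_barriers = 5, L = 1e5,
                                      mean_stride = 500) {
  repeat {
    rev <- sort(sample.int(L, n_lefs) - 1)
    gap <- sample.int(round(L / 20), n_lefs)
    fwd <- pmin(rev + gap, L - 1)
    if (length(unique(c(rev, fwd))) == 2 * n_lefs) break
  }
  barriers <- data.frame(
    pos = sample.int(L, n_barriers) - 1,
    blocking = sample(c("reverse", "forward"), n_barriers, replace = TRUE),
    bound = runif(n_barriers) < 0.7,
    stringsAsFactors = FALSE
  )
  list(
    lefs = data.frame(rev = rev, fwd = fwd),
    rev_stride = pmax(round(rnorm(n_lefs, mean_stride, mean_stride / 4)), 0),
    fwd_stride = pmax(round(rnorm(n_lefs, mean_stride, mean_stride / 4)), 0),
    barriers = barriers,
    L = L
  )
}

# Small, fast simulation configuration for engine tests.
tiny_config <- function(...) {
  sim_config(bin_size = 10000, diagonal_width = 400e3, ncells = 4,
             target_contact_density = 1, ...)
}
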