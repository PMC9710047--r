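test_that("LEF binding is uniform and starts with zero-size loops", {
  set.seed(3)
  expect_equal(nrow(bind_lefs(0, 1e6)), 0)
  lefs <- bind_lefs(1e5, 1e6)
  expect_true(all(lefs$rev == lefs$fwd))  # fresh loops have size 0
  ks <- suppressWarnings(ks.test(lefs$rev / 1e6, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("unit indexing orders both unit classes 5'->3'", {
  lefs <- data.frame(rev = c(5, 1, 3), fwd = c(9, 2, 3))
  idx <- index_units(lefs)
  expect_equal(idx$rev_order, c(2, 3, 1))
  expect_equal(idx$fwd_order, c(2, 3, 1))
  sorted <- data.frame(rev = 1:4, fwd = 2:5)
  expect_equal(index_units(sorted)$rev_order, 1:4)
  set.seed(1)
  r <- runif(50)
  expect_equal(index_units(data.frame(rev = r, fwd = r))$rev_order, order(r))
})

test_that("strides follow a truncated normal with the configured moments", {
  set.seed(4)
  s <- generate_moves(1e5, 5000, 0.05)
  expect_true(all(s == round(s) & s >= 0))
  expect_lt(abs(mean(s) - 5000), 3 * 250 / sqrt(1e5))
  expect_equal(generate_moves(100, 5000, 0), rep(5000, 100))
})

test_that("single-unit collisions follow the blocking and boundary rules", {
  # forward unit vs Bound forward-blocking ('-') barrier: stop 1 bp short
  lefs <- data.frame(rev = 10000, fwd = 10000)
  bars <- data.frame(pos = 12000, blocking = "forward", bound = TRUE)
  res <- detect_and_resolve_collisions(lefs, 5000, 5000, bars, 1e6)
  expect_equal(res$fwd, 11999)
  expect_equal(res$fwd_stall, "barrier")
  expect_equal(res$rev, 5000)
  expect_equal(res$rev_stall, "none")

  # unbound barrier is fully transparent
  bars$bound <- FALSE
  res <- detect_and_resolve_collisions(lefs, 5000, 5000, bars, 1e6)
  expect_equal(res$fwd, 15000)
  expect_equal(res$fwd_stall, "none")

  # barrier in the non-blocking orientation is transparent too
  bars <- data.frame(pos = 12000, blocking = "reverse", bound = TRUE)
  res <- detect_and_resolve_collisions(lefs, 5000, 5000, bars, 1e6)
  expect_equal(res$fwd, 15000)

  # reverse unit clipped at the chromosome start (no stall mark)
  lefs <- data.frame(rev = 100, fwd = 200)
  res <- detect_and_resolve_collisions(
    lefs, 500, 0, data.frame(pos = numeric(), blocking = character(),
                             bound = logical()), 1e6)
  expect_equal(res$rev, 0)
  expect_equal(res$rev_stall, "none")
})

test_that("collision resolution matches the 1-bp micro-stepping oracle", {
  for (rep in 1:25) {
    set.seed(100 + rep)
    inst <- random_collision_instance(n_lefs = 8, n_barriers = 6, L = 1e5,
                                      mean_stride = 400)
    got <- detect_and_resolve_collisions(inst$lefs, inst$rev_stride,
                                         inst$fwd_stride, inst$barriers,
                                         inst$L)
    want <- micro_step_oracle(inst$lefs$rev, inst$lefs$fwd, inst$rev_stride,
                              inst$fwd_stride, inst$barriers, inst$L)
    expect_equal(got$rev, want$rev, info = paste("rev rep", rep))
    expect_equal(got$fwd, want$fwd, info = paste("fwd rep", rep))
    expect_equal(got$rev_stall, want$rev_stall, info = paste("revs", rep))
    expect_equal(got$fwd_stall, want$fwd_stall, info = paste("fwds", rep))
  }
})

test_that("post-epoch safety invariants hold on dense random systems", {
  # many LEFs and barriers on a short chromosome: heavy collision traffic
  for (rep in 1:10) {
    set.seed(200 + rep)
    inst <- random_collision_instance(n_lefs = 40, n_barriers = 20, L = 5e4,
                                      mean_stride = 800)
    got <- detect_and_resolve_collisions(inst$lefs, inst$rev_stride,
                                         inst$fwd_stride, inst$barriers,
                                         inst$L)
    # loop size stays non-negative
    expect_true(all(got$fwd - got$rev >= 0))
    # genomic unit order is preserved (no crossings)
    before <- order(c(inst$lefs$rev, inst$lefs$fwd))
    after <- c(got$rev, got$fwd)
    expect_true(all(diff(after[before]) >= 0))
    # no unit sits strictly beyond a Bound blocking barrier it crossed
    bound <- inst$barriers[inst$barriers$bound, ]
    for (i in seq_along(got$fwd)) {
      crossed <- bound$blocking == "forward" &
        bound$pos > inst$lefs$fwd[i] & bound$pos <= got$fwd[i]
      expect_true(!any(crossed))
      crossed <- bound$blocking == "reverse" &
        bound$pos < inst$lefs$rev[i] & bound$pos >= got$rev[i]
      expect_true(!any(crossed))
    }
  }
})

test_that("release probability and the hard-stall extension behave as configured", {
  set.seed(5)
  # base rate 2 * stride / processivity
  rel <- release_lefs(rep(FALSE, 2e5), 5000, 200e3)
  expect_lt(abs(mean(rel) - 0.05), 3 * sqrt(0.05 * 0.95 / 2e5))
  # neutral multiplier: stalled and unstalled share the release law
  rel_stalled <- release_lefs(rep(TRUE, 2e5), 5000, 200e3,
                              hard_stall_multiplier = 1)
  expect_lt(abs(mean(rel_stalled) - 0.05), 3 * sqrt(0.05 * 0.95 / 2e5))
  # multiplier 5 cuts the rate five-fold
  rel5 <- release_lefs(rep(TRUE, 2e5), 5000, 200e3, hard_stall_multiplier = 5)
  expect_lt(abs(mean(rel5) - 0.01), 3 * sqrt(0.01 * 0.99 / 2e5))
  expect_warning(release_lefs(FALSE, 5000, 8000), "clamped")
})

test_that("LEF lifetimes are geometric with mean processivity / (2 stride)", {
  chroms <- data.frame(name = "chrT", length = 1e6)
  cfg <- sim_config(bin_size = 10e3, diagonal_width = 200e3, ncells = 2,
                    processivity = 100e3, mean_stride = 2500,
                    target_epochs = 1500, burn_in_max_epochs = 0, seed = 9)
  res <- run_simulation(chroms, NULL, cfg, collect_lifetimes = TRUE)
  lt <- res$lifetimes
  expect_gt(length(lt), 2000)
  p <- 2 * 2500 / 100e3  # 0.05, mean lifetime 20 epochs
  expect_lt(abs(mean(lt) - 20), 3 * (sqrt(1 - p) / p) / sqrt(length(lt)))
  # chi-squared goodness of fit against the geometric pmf
  breaks <- c(1:40, Inf)
  obs <- table(cut(lt, c(0, breaks)))
  probs <- diff(c(0, pgeom(breaks - 1, p)))
  gof <- chisq.test(as.numeric(obs), p = probs)
  expect_gt(gof$p.value, 0.01)
})

test_that("runs are deterministic and scheduling-order invariant", {
  spec <- toy_spec(lengths = c(chrA = 6e5, chrB = 4e5), n_pairs = 1,
                   occupancy = 0.9, seed = 1)
  chroms <- make_toy_genome(spec)
  barriers <- make_barrier_annotation(spec)
  cfg <- sim_config(bin_size = 10e3, diagonal_width = 200e3, ncells = 4,
                    target_contact_density = 0.5, seed = 42)
  r1 <- run_simulation(chroms, barriers, cfg)
  r2 <- run_simulation(chroms, barriers, cfg)
  ntasks <- nrow(make_tasks(chroms, cfg))
  r3 <- run_simulation(chroms, barriers, cfg, task_order = ntasks:1)
  for (cn in chroms$name) {
    expect_identical(cm_pixels(r1$matrices[[cn]]), cm_pixels(r2$matrices[[cn]]))
    expect_identical(cm_pixels(r1$matrices[[cn]]), cm_pixels(r3$matrices[[cn]]))
  }
  # a different master seed changes the output
  cfg2 <- cfg
  cfg2$seed <- 43L
  r4 <- run_simulation(chroms, barriers, cfg2)
  expect_false(identical(cm_pixels(r1$matrices$chrA),
                         cm_pixels(r4$matrices$chrA)))
})

test_that("the density stopping rule reaches the target", {
  spec <- toy_spec(lengths = c(chrT = 1e6), n_pairs = 2, seed = 2)
  chroms <- make_toy_genome(spec)
  cfg <- tiny_config(seed = 7)
  res <- run_simulation(chroms, make_barrier_annotation(spec), cfg)
  expect_gte(res$report$mean_density["chrT"][[1]], 1)
  expect_gt(res$report$burnin_epochs_per_chrom[["chrT"]], 0)
})

test_that("a convergent Bound pair builds a corner dot", {
  chroms <- data.frame(name = "chrT", length = 1e6)
  barriers <- data.frame(
    chrom = "chrT", pos = c(250e3, 750e3),
    blocking = c("reverse", "forward"), occupancy = 0.99, puu = 0.99,
    stringsAsFactors = FALSE
  )
  # sparse, processive LEFs so 500-kbp loops are reachable before LEF-LEF
  # collisions hem them in
  cfg <- sim_config(bin_size = 10e3, diagonal_width = 600e3, ncells = 8,
                    lef_density = 4, processivity = 2e6,
                    hard_stall_multiplier = 20,
                    target_contact_density = 1, seed = 13)
  with_b <- run_simulation(chroms, barriers, cfg)
  no_b <- run_simulation(chroms, NULL, cfg)
  dot <- function(m) {
    s <- 0
    for (i in 23:27) for (j in 72:77) s <- s + cm_get(m, i, j)
    s
  }
  expect_gt(dot(with_b$matrices$chrT), 2 * dot(no_b$matrices$chrT))
})

test_that("deleting a barrier region removes its occupancy", {
  spec <- toy_spec(lengths = c(chrT = 1e6), n_pairs = 2, occupancy = 0.95,
                   seed = 4)
  chroms <- make_toy_genome(spec)
  barriers <- make_barrier_annotation(spec)
  del <- data.frame(chrom = "chrT", start = 0, end = 5e5)
  prepped <- extrusim:::prepare_barriers(barriers, chroms, deleted_regions = del)
  expect_true(all(prepped$occupancy[prepped$pos < 5e5] == 0))
  expect_true(all(prepped$occupancy[prepped$pos >= 5e5] == 0.95))
})

test_that("LEF occupancy tracks peak at a strong convergent pair", {
  chroms <- data.frame(name = "chrT", length = 1e6)
  barriers <- data.frame(
    chrom = "chrT", pos = c(400e3, 600e3),
    blocking = c("reverse", "forward"), occupancy = 0.99, puu = 0.99,
    stringsAsFactors = FALSE
  )
  cfg <- sim_config(bin_size = 10e3, diagonal_width = 400e3, ncells = 4,
                    processivity = 800e3, target_contact_density = 1,
                    seed = 21)
  res <- run_simulation(chroms, barriers, cfg, record_tracks = TRUE)
  track <- lef_occupancy_track(res, chroms)
  expect_equal(sum(track$value), sum(res$tracks$chrT))
  at_barrier <- mean(track$value[track$start %in% c(400e3, 600e3)])
  flank <- mean(track$value[track$start %in% c(300e3, 350e3, 650e3, 700e3)])
  expect_gt(at_barrier, 1.5 * flank)
})

test_that("zero LEFs exit immediately (degenerate instance)", {
  par <- list(bin_size = 1000, band_rows = 10L, mean_stride = 100,
              stride_sd = 0, p_release = 0.1, hard_mult = 1,
              sampling_fraction = 0.5, tad_ratio = 0, contact_mode = 0L,
              target_contacts = 10, max_epochs = 100L,
              burn_in_window = 4L, burn_in_tol = 0.05, burn_in_max = 100L,
              track_bin = 0, collect_lifetimes = FALSE)
  res <- extrusim:::simulate_cell_cpp(1e5, 0L, numeric(0), integer(0),
                                      numeric(0), numeric(0), numeric(0), par)
  expect_equal(res$epochs, 0)
  expect_equal(res$contacts, 0)
})
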