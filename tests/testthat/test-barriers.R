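# Simulate a single two-state chain for n steps starting from its
# stationary distribution; returns the visited states. Written as a plain
# loop, independent of step_barrier_states().
simulate_chain <- function(puu, pbb, n, seed) {
  set.seed(seed)
  s <- logical(n)
  state <- runif(1) < stationary_occupancy(puu, pbb)
  u <- runif(n)
  for (i in seq_len(n)) {
    state <- if (state) u[i] < pbb else u[i] >= puu
    s[i] <- state
  }
  s
}

test_that("occupancy/transition algebra matches the closed forms", {
  # the optimizer-default operating point: occupancy 0.747 with P_UU 0.963
  pbb <- occupancy_to_pbb(0.747, 0.963)
  expect_equal(pbb, 1 - (1 - 0.963) * (1 - 0.747) / 0.747)
  expect_equal(pbb, 0.987469, tolerance = 1e-6)
  expect_equal(stationary_occupancy(0.963, pbb), 0.747)

  # symmetric chain: occupancy 1/2 forces P_BB = P_UU
  for (p in c(0, 0.3, 0.99)) expect_equal(occupancy_to_pbb(0.5, p), p)
  expect_equal(stationary_occupancy(0.4, 0.4), 0.5)
  expect_equal(stationary_occupancy(0.9, 0.99), 0.1 / 0.11)

  # limits and infeasibility
  expect_equal(occupancy_to_pbb(1, 0.5), 1)
  expect_equal(occupancy_to_pbb(0, 0.5), 0)
  expect_error(occupancy_to_pbb(0.1, 0.0), "infeasible")
  expect_equal(occupancy_to_pbb(0.1, 0.0, clamp = TRUE), 0)
  expect_error(stationary_occupancy(1, 1), "undefined")
})

test_that("algebra round-trips over a grid of feasible pairs", {
  grid <- expand.grid(occ = seq(0.05, 0.95, by = 0.09),
                      puu = seq(0.05, 0.95, by = 0.09))
  feasible <- grid$occ >= (1 - grid$puu) / (2 - grid$puu)
  grid <- grid[feasible, ]
  pbb <- occupancy_to_pbb(grid$occ, grid$puu)
  expect_true(all(pbb >= 0 & pbb <= 1))
  expect_equal(stationary_occupancy(grid$puu, pbb), grid$occ,
               tolerance = 1e-12)
})

test_that("empirical chain occupancy converges to the stationary value", {
  puu <- 0.963
  pbb <- occupancy_to_pbb(0.747, puu)
  n <- 1e6
  s <- simulate_chain(puu, pbb, n, seed = 11)
  # autocorrelated samples: SE inflated by the integrated autocorrelation
  # time (1 + lambda) / (1 - lambda), lambda = puu + pbb - 1
  lambda <- puu + pbb - 1
  se <- sqrt(0.747 * 0.253 * (1 + lambda) / (1 - lambda) / n)
  expect_lt(abs(mean(s) - 0.747), 3 * se)
})

test_that("Bound dwell times are geometric with mean 1 / (1 - P_BB)", {
  pbb <- 0.9
  puu <- 0.8
  s <- simulate_chain(puu, pbb, 4e5, seed = 5)
  runs <- rle(s)
  dwell <- runs$lengths[runs$values]
  dwell <- dwell[-c(1, length(dwell))]  # drop possibly censored ends
  se <- sd(dwell) / sqrt(length(dwell))
  expect_lt(abs(mean(dwell) - 1 / (1 - pbb)), 3 * se)
})

test_that("state stepping honors absorbing limits and zero occupancy", {
  set.seed(1)
  # P_BB = 1: Bound forever
  s <- rep(TRUE, 100)
  for (i in 1:50) s <- step_barrier_states(s, puu = 0.5, pbb = 1)
  expect_true(all(s))
  # P_UU = 1: Unbound forever
  s <- rep(FALSE, 100)
  for (i in 1:50) s <- step_barrier_states(s, puu = 1, pbb = 0.5)
  expect_true(all(!s))
  # occupancy 0 pins the state Unbound regardless of transitions
  s <- rep(FALSE, 100)
  for (i in 1:50) s <- step_barrier_states(s, puu = 0.2, pbb = 0.9,
                                           occupancy = rep(0, 100))
  expect_true(all(!s))
})

test_that("initial states are Bernoulli draws at the occupancy", {
  set.seed(2)
  expect_true(all(init_barrier_state(rep(1, 50))))
  expect_true(all(!init_barrier_state(rep(0, 50))))
  n <- 1e5
  frac <- mean(init_barrier_state(rep(0.3, n)))
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("ChIP-seq signal maps through the logistic to occupancies", {
  # logistic midpoint and saturation
  tr <- data.frame(chrom = "chrT", start = c(0, 1000), end = c(1000, 2000),
                   value = c(1.0, 1e6))
  occ <- occupancy_from_chipseq(tr, midpoint = 1, steepness = 2,
                                max_occupancy = 0.9)
  expect_equal(occ$occupancy[1], 0.45)      # x = midpoint -> max / 2
  expect_equal(occ$occupancy[2], 0.9)       # x -> Inf -> max
  # two 1-kbp bins from a 2-kbp signal vector [0,0,10,10] at 500 bp steps
  tr <- data.frame(chrom = "chrT", start = c(0, 500, 1000, 1500),
                   end = c(500, 1000, 1500, 2000), value = c(0, 0, 10, 10))
  occ <- occupancy_from_chipseq(tr, midpoint = 1, steepness = 2,
                                max_occupancy = 0.9)
  expect_equal(nrow(occ), 2)
  expect_lt(occ$occupancy[1], 0.15)
  expect_equal(occ$occupancy[2], 0.9, tolerance = 1e-6)
  expect_error(occupancy_from_chipseq(
    data.frame(chrom = "c", start = 0, end = 10, value = -1)), "negative")
})

test_that("occupancy normalization to a reference P_UU is invertible", {
  occ <- c(0.4, 0.6, 0.9, 0)
  puu <- c(0.5, 0.9, 0.95, 0.7)
  norm <- normalize_occupancy(occ, puu, reference_puu = 0.7)
  expect_equal(norm[4], 0)
  # a barrier already at the reference P_UU is unchanged
  expect_equal(normalize_occupancy(0.6, 0.7, 0.7), 0.6)
  # round trip: re-normalizing to the original P_UU recovers the occupancy
  back <- mapply(function(o, p) normalize_occupancy(o, 0.7, p), norm, puu)
  expect_equal(back, occ, tolerance = 1e-9)
})

test_that("barrier occupancy track bins and normalizes per barrier", {
  b <- data.frame(chrom = "chrT", pos = c(1500, 1700, 5200),
                  blocking = "reverse", occupancy = c(0.4, 0.8, 0.6),
                  puu = 0.7)
  chroms <- data.frame(name = "chrT", length = 10e3)
  tr <- barrier_occupancy_track(b, chroms, bin_size = 1000)
  expect_equal(tr$start, c(1000, 5000))
  expect_equal(tr$value, c(0.8, 0.6))  # bin maximum
  trn <- barrier_occupancy_track(b, chroms, reference_puu = 0.7,
                                 bin_size = 1000)
  expect_equal(trn$value, tr$value)    # same P_UU: identity
})
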