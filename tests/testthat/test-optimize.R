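test_that("the occupancy penalty has the prescribed shape and bounds", {
  grid <- seq(0, 1, length.out = 1e4)
  p <- penalty(grid)
  expect_true(all(p >= 1 & p <= 2))
  expect_equal(penalty(0.5), 2)
  expect_lte(penalty(0), 1.001)
  expect_gt(penalty(1), penalty(0.9))      # near-1 occupancies penalized
  expect_lt(penalty(0.05), penalty(0.3))   # falls toward the extremes
  expect_error(penalty(1.2), "outside")
  expect_error(penalty(-0.1), "outside")
})

test_that("two-point crossover conserves genes per locus", {
  set.seed(8)
  n <- 12
  p1 <- extrusim:::new_individual(n)
  p2 <- extrusim:::new_individual(n)
  for (i in 1:20) {
    off <- mate(p1, p2)
    for (v in c("occupancy", "puu")) {
      for (l in seq_len(n)) {
        expect_setequal(c(off[[1]][[v]][l], off[[2]][[v]][l]),
                        c(p1[[v]][l], p2[[v]][l]))
      }
    }
  }
  # identical parents always produce identical offspring
  off <- mate(p1, p1)
  expect_equal(off[[1]], p1)
  expect_equal(off[[2]], p1)
})

test_that("mutation is clamped Gaussian noise that respects masks", {
  set.seed(9)
  ind <- list(occupancy = rep(0.5, 1000), puu = rep(0.5, 1000))
  m <- mutate(ind, sd = 0.05)
  offsets <- m$occupancy - 0.5
  expect_lt(abs(mean(offsets)), 3 * 0.05 / sqrt(1000))
  expect_lt(abs(sd(offsets) - 0.05), 0.01)
  # sd -> 0 is the identity
  expect_equal(mutate(ind, 0), ind)
  # clamping keeps genes inside [0, 1]
  hi <- list(occupancy = rep(1, 500), puu = rep(0, 500))
  m <- mutate(hi, sd = 0.5)
  expect_true(all(m$occupancy <= 1 & m$occupancy >= 0))
  expect_true(all(m$puu >= 0 & m$puu <= 1))
  # masked genes never move
  mask <- rep(c(TRUE, FALSE), 500)
  m <- mutate(ind, sd = 0.3, mask = mask)
  expect_equal(m$occupancy[mask], ind$occupancy[mask])
  expect_equal(m$puu[mask], ind$puu[mask])
  expect_true(any(m$occupancy[!mask] != ind$occupancy[!mask]))
})

test_that("one evolution stage keeps the top-mu offspring, sorted by fitness", {
  set.seed(10)
  fit <- function(ind, active) mean((ind$occupancy - 0.7)^2)
  pop <- lapply(1:6, function(i) extrusim:::new_individual(5))
  stage <- extrusim:::evolve(pop, fit, ga_config(mu = 6, lambda = 12,
                                                 n_islands = 0),
                             mu = 6, lambda = 12, max_generations = 3)
  expect_length(stage$pop, 6)
  expect_equal(stage$fits, sort(stage$fits))
  expect_equal(stage$fits, vapply(stage$pop, fit, numeric(1),
                                  active = rep(TRUE, 5)))
})

test_that("the evolution strategy recovers an analytic optimum", {
  set.seed(11)
  fit <- function(ind, active)
    mean((ind$occupancy - 0.9)^2) + mean((ind$puu - 0.3)^2)
  res <- run_ga(fit, n_genes = 4,
                ga_config(mu = 8, lambda = 16, max_generations = 60,
                          mutation_sd = 0.08, n_islands = 0))
  expect_lt(mean(abs(res$best$occupancy - 0.9)), 0.12)
  expect_lt(mean(abs(res$best$puu - 0.3)), 0.12)
  expect_true(all(abs(res$best$occupancy - 0.9) < 0.25))
  expect_true(all(abs(res$best$puu - 0.3) < 0.25))
  # history carries per-generation best and mean fitness
  expect_true(all(c("stage", "generation", "best", "mean") %in%
                    names(res$history)))
})

test_that("the island phase masks barriers, replaces weak alleles, and migrates", {
  set.seed(12)
  seen_active <- list()
  fit <- function(ind, active) {
    seen_active[[length(seen_active) + 1L]] <<- active
    mean((ind$occupancy - 0.8)^2) + 0.1 * mean((ind$puu - 0.5)^2)
  }
  res <- run_ga(fit, n_genes = 10,
                ga_config(mu = 6, lambda = 12, max_generations = 5,
                          island_mu = 4, island_lambda = 8, n_islands = 2,
                          mask_mean = 3, mask_sd = 1, n_cycles = 1))
  stages <- unique(res$history$stage)
  expect_true(any(grepl("island-1-1", stages)))
  expect_true(any(grepl("island-1-2", stages)))
  expect_true(any(grepl("mainland-2", stages)))
  # the masked island really deactivated a consecutive stretch
  masked <- Filter(function(a) !all(a), seen_active)
  expect_gt(length(masked), 0)
  runs <- rle(masked[[1]])
  expect_equal(sum(!masked[[1]]), sum(runs$lengths[!runs$values]))
  expect_equal(sum(!runs$values), 1)  # one consecutive masked block
})

test_that("GP expected-improvement minimization finds a quadratic optimum", {
  set.seed(13)
  fn <- function(x) (x[1] - 0.3)^2 + (x[2] - 0.7)^2
  res <- minimize_gp(fn, lower = c(0, 0), upper = c(1, 1), n_calls = 30)
  expect_lt(abs(res$par[1] - 0.3), 0.1)
  expect_lt(abs(res$par[2] - 0.7), 0.1)
  expect_equal(nrow(res$trace), 30)
  expect_true(all(diff(res$trace$best_so_far) <= 0))
  # a single call returns that single evaluation
  one <- minimize_gp(fn, c(0, 0), c(1, 1), n_calls = 1)
  expect_equal(nrow(one$trace), 1)
  expect_equal(one$value, fn(one$par))
})

test_that("the genome-wide objective is zero on self-comparison and bounded", {
  spec <- toy_spec(lengths = c(chrT = 1e6), n_pairs = 2, occupancy = 0.85,
                   puu = 0.9, seed = 31)
  simcfg <- sim_config(bin_size = 10e3, diagonal_width = 400e3, ncells = 4,
                       seed = 31)
  ref <- make_reference_matrix(spec, config = simcfg)
  stripes <- make_toy_stripes(spec, bin_size = 10e3, pad_bins = 3)
  cfg <- gw_config(ref$chroms, ref$barriers, ref$matrices, stripes,
                   config = simcfg, ref_threshold = 0.75,
                   sim_threshold = 0.75, seed = 31)
  # same parameters, same seed: the simulation reproduces the reference
  self <- gw_objective(0.85, 0.9, cfg)
  expect_equal(self$training, 0)
  expect_equal(self$validation, 0)
  # infeasible pair scores the maximal dissimilarity
  inf <- gw_objective(0.05, 0.9, cfg)
  expect_true(inf$infeasible)
  expect_equal(inf$training, 1)
  # a wrong occupancy scores strictly worse than the truth
  wrong <- gw_objective(0.3, 0.9, cfg)
  expect_gt(wrong$training, self$training)
  expect_true(wrong$training >= 0 && wrong$training <= 1)
  # training and validation stripe sets are disjoint halves
  expect_equal(sum(cfg$stripes$set == "training"), nrow(stripes) %/% 2)
})
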