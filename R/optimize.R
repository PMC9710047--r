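# Barrier-parameter fitting against a reference contact matrix.
#
# Two routes:
#  * optimize_gw(): a uniform (occupancy, P_UU) pair for all barriers,
#    minimized by Gaussian-process Bayesian optimization (expected
#    improvement over a box).
#  * run_ga(): per-barrier occupancy and P_UU via a (mu, lambda) evolution
#    strategy with two-point crossover, clamped Gaussian mutation, a
#    penalty keeping occupancies away from the uninformative mid-range, and
#    an island model with barrier masking.

#' Mid-occupancy penalty for the genetic fitness
#'
#' A coefficient in \[1, 2\]: close to 2 when the occupancy approaches 0.5
#' (where the stripe score carries little signal), falling rapidly to 1
#' toward 0 and toward 1, with a secondary bump penalizing occupancies very
#' close to 1. Implemented as two Gaussian bumps clipped at 2:
#' `p(x) = min(2, 1 + exp(-(x-0.5)^2 / (2*0.12^2))
#'              + 0.5*exp(-(x-1)^2 / (2*0.02^2)))`.
#'
#' @param occupancy Values in \[0, 1\].
#' @return Penalty coefficients, vectorized.
#' @export
penalty <- function(occupancy) {
  if (any(occupancy < 0 | occupancy > 1))
    stop("occupancy outside [0, 1]")
  pmin(2, 1 + exp(-(occupancy - 0.5)^2 / (2 * 0.12^2)) +
         0.5 * exp(-(occupancy - 1)^2 / (2 * 0.02^2)))
}

## ---------------------------------------------------------------------------
## Gaussian-process expected-improvement minimizer

# Squared-exponential kernel on inputs scaled to [0,1]^d.
gp_kernel <- function(X1, X2, ell, sigf2) {
  d2 <- matrix(0, nrow(X1), nrow(X2))
  for (j in seq_len(ncol(X1)))
    d2 <- d2 + outer(X1[, j], X2[, j], "-")^2 / ell[j]^2
  sigf2 * exp(-0.5 * d2)
}

gp_fit <- function(X, y) {
  d <- ncol(X)
  mu <- mean(y)
  sy <- sd(y)
  if (!is.finite(sy) || sy == 0) sy <- 1
  yc <- (y - mu) / sy
  nll <- function(theta) {
    ell <- exp(theta[1:d])
    sigf2 <- exp(theta[d + 1])
    sign2 <- exp(theta[d + 2])
    K <- gp_kernel(X, X, ell, sigf2) + diag(sign2 + 1e-8, nrow(X))
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    alpha <- backsolve(ch, forwardsolve(t(ch), yc))
    as.numeric(0.5 * sum(yc * alpha) + sum(log(diag(ch))))
  }
  theta0 <- c(rep(log(0.3), d), log(1), log(0.1))
  opt <- optim(theta0, nll, method = "L-BFGS-B",
               lower = c(rep(log(0.03), d), log(1e-3), log(1e-6)),
               upper = c(rep(log(3), d), log(30), log(2)))
  ell <- exp(opt$par[1:d])
  sigf2 <- exp(opt$par[d + 1])
  sign2 <- exp(opt$par[d + 2])
  K <- gp_kernel(X, X, ell, sigf2) + diag(sign2 + 1e-8, nrow(X))
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  list(X = X, ch = ch, alpha = alpha, ell = ell, sigf2 = sigf2,
       mu = mu, sy = sy)
}

gp_predict <- function(fit, Xnew) {
  Ks <- gp_kernel(fit$X, Xnew, fit$ell, fit$sigf2)
  m <- drop(crossprod(Ks, fit$alpha))
  v <- forwardsolve(t(fit$ch), Ks)
  s2 <- pmax(fit$sigf2 - colSums(v^2), 1e-12)
  list(mean = fit$mu + fit$sy * m, sd = fit$sy * sqrt(s2))
}

expected_improvement <- function(mean, sd, best) {
  z <- (best - mean) / sd
  (best - mean) * pnorm(z) + sd * dnorm(z)
}

#' Minimize a black-box function over a box by GP expected improvement
#'
#' Sequential model-based minimization: a latin-hypercube initial design,
#' then, per call, a squared-exponential Gaussian process (ML-II
#' hyperparameters, fitted noise) and expected-improvement maximization over
#' a random candidate set.
#'
#' @param fn Function of a numeric vector, returning a scalar to minimize.
#' @param lower,upper Box bounds.
#' @param n_calls Total function evaluations.
#' @param n_init Initial design size (default `min(10, n_calls)`).
#' @param n_candidates Candidate points per EI maximization.
#' @return list with `par`, `value`, and an evaluation data.frame `trace`
#'   (inputs, value, running best).
#' @export
minimize_gp <- function(fn, lower, upper, n_calls = 40,
                        n_init = min(10L, n_calls), n_candidates = 512) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower), n_calls >= 1)
  n_init <- min(n_init, n_calls)
  scale_up <- function(U) sweep(sweep(U, 2, upper - lower, "*"), 2, lower, "+")
  X <- matrix(numeric(0), 0, d)
  y <- numeric(0)
  evaluate <- function(x) fn(x)
  X0 <- scale_up(lhs::randomLHS(n_init, d))
  for (i in seq_len(n_init)) {
    X <- rbind(X, X0[i, ])
    y <- c(y, evaluate(X0[i, ]))
  }
  while (length(y) < n_calls) {
    fit <- tryCatch(gp_fit(sweep(sweep(X, 2, lower, "-"), 2, upper - lower, "/"), y),
                    error = function(e) NULL)
    if (is.null(fit)) {
      xnew <- scale_up(matrix(runif(d), 1))
    } else {
      Uc <- lhs::randomLHS(n_candidates, d)
      # local refinement around the incumbent
      best_u <- (X[which.min(y), ] - lower) / (upper - lower)
      loc <- matrix(rep(best_u, each = 64), 64, d) +
        matrix(rnorm(64 * d, 0, 0.05), 64, d)
      Uc <- rbind(Uc, pmin(pmax(loc, 0), 1))
      pr <- gp_predict(fit, Uc)
      ei <- expected_improvement(pr$mean, pr$sd, min(y))
      xnew <- scale_up(Uc[which.max(ei), , drop = FALSE])
    }
    X <- rbind(X, as.numeric(xnew))
    y <- c(y, evaluate(as.numeric(xnew)))
  }
  trace <- as.data.frame(X)
  names(trace) <- paste0("x", seq_len(d))
  trace$value <- y
  trace$best_so_far <- cummin(y)
  best <- which.min(y)
  list(par = as.numeric(X[best, ]), value = y[best], trace = trace)
}

## ---------------------------------------------------------------------------
## Genome-wide objective (uniform parameters)

#' Configuration for the genome-wide stripe-dissimilarity objective
#'
#' @param chroms Chromosome data.frame.
#' @param barriers Barrier annotation (positions/directions are kept; the
#'   objective overrides occupancy and P_UU with the proposed uniform pair).
#' @param reference Named list of reference [banded_matrix()] objects (raw
#'   counts), one per chromosome.
#' @param stripes Stripe annotation data.frame with `chrom`, `start`, `end`,
#'   `orientation` (`"H"` horizontal: intersected with row scores; `"V"`
#'   vertical: with column scores).
#' @param config A [sim_config()] used for each candidate simulation.
#' @param sigma1,sigma2 DoG widths.
#' @param ref_threshold,sim_threshold Discretization thresholds for the
#'   reference and the simulated matrix.
#' @param seed Seed for the train/validation stripe split and for each
#'   candidate simulation (fixed across calls, so the objective is
#'   deterministic in its parameters).
#' @return list of class `gw_config`, with reference band images
#'   pre-transformed and stripes split into disjoint training/validation
#'   halves.
#' @export
gw_config <- function(chroms, barriers, reference, stripes,
                      config = sim_config(), sigma1 = 1.0, sigma2 = 1.6,
                      ref_threshold = 1.5, sim_threshold = 0.75, seed = 0) {
  stopifnot(all(stripes$orientation %in% c("H", "V")))
  ref_bands <- lapply(chroms$name, function(cn)
    discretize(dog_transform(band_image(reference[[cn]]), sigma1, sigma2),
               ref_threshold))
  names(ref_bands) <- chroms$name
  set.seed(seed)
  n <- nrow(stripes)
  train_idx <- sample.int(n, floor(n / 2))
  stripes$set <- "validation"
  stripes$set[train_idx] <- "training"
  structure(list(chroms = chroms, barriers = barriers, ref_bands = ref_bands,
                 stripes = stripes, sim_config = config,
                 sigma1 = sigma1, sigma2 = sigma2,
                 sim_threshold = sim_threshold, seed = seed),
            class = "gw_config")
}

# Mean stripe-end mismatch over the bins covered by a stripe set.
stripe_mismatch <- function(scores, stripes, chroms, bin_size, set) {
  st <- stripes[stripes$set == set, , drop = FALSE]
  vals <- numeric(0)
  for (r in seq_len(nrow(st))) {
    cn <- st$chrom[r]
    b0 <- floor(st$start[r] / bin_size)
    b1 <- max(b0, ceiling(st$end[r] / bin_size) - 1)
    nb <- length(scores[[cn]]$rows)
    bins <- (b0:b1)[b0:b1 >= 0 & b0:b1 < nb] + 1L
    v <- if (st$orientation[r] == "H") scores[[cn]]$rows[bins]
         else scores[[cn]]$cols[bins]
    vals <- c(vals, v)
  }
  mean(vals, na.rm = TRUE)
}

#' Genome-wide dissimilarity objective for a uniform (occupancy, P_UU) pair
#'
#' Simulates the genome with the proposed uniform parameters, transforms the
#' result (DoG + discretization), scores stripe-end mismatches row- and
#' column-wise against the transformed reference, intersects horizontal
#' stripes with row scores and vertical stripes with column scores, and
#' averages. Infeasible pairs (occupancy too small for the given P_UU) score
#' the maximal dissimilarity 1.
#'
#' @param occupancy,puu Proposed uniform parameters in (0, 1).
#' @param config A [gw_config()].
#' @return list with `training` and `validation` mean mismatch (lower is
#'   better) and `infeasible` flag.
#' @export
gw_objective <- function(occupancy, puu, config) {
  feasible <- occupancy > 0 &&
    occupancy >= (1 - puu) / (2 - puu) - 1e-12
  if (!feasible)
    return(list(training = 1, validation = 1, infeasible = TRUE))
  b <- config$barriers
  b$occupancy <- occupancy
  b$puu <- puu
  cfg <- config$sim_config
  cfg$seed <- config$seed
  sim <- run_simulation(config$chroms, b, cfg)
  scores <- lapply(config$chroms$name, function(cn) {
    tb <- discretize(dog_transform(band_image(sim$matrices[[cn]]),
                                   config$sigma1, config$sigma2),
                     config$sim_threshold)
    score_matrices(config$ref_bands[[cn]], tb, mode = "dissimilarity")
  })
  names(scores) <- config$chroms$name
  list(
    training = stripe_mismatch(scores, config$stripes, config$chroms,
                               cfg$bin_size, "training"),
    validation = stripe_mismatch(scores, config$stripes, config$chroms,
                                 cfg$bin_size, "validation"),
    infeasible = FALSE
  )
}

#' Bayesian optimization of the uniform barrier parameters
#'
#' Minimizes [gw_objective()] over an (occupancy, P_UU) box with
#' [minimize_gp()]. The training score drives the optimizer; the validation
#' score is recorded per call but never influences it.
#'
#' @param config A [gw_config()].
#' @param lower,upper Bounds for `c(occupancy, puu)`, inside (0, 1).
#' @param n_calls Objective evaluations; the 400-call default suits
#'   genome-scale fits, scaled-down problems need far fewer.
#' @return list with `occupancy`, `puu`, `value` (best training score) and
#'   `trace` (per-call occupancy, puu, training, validation, running best).
#' @export
optimize_gw <- function(config, lower = c(0.5, 0.5), upper = c(0.995, 0.995),
                        n_calls = 400) {
  stopifnot(all(lower > 0), all(upper < 1))
  validation <- numeric(0)
  fn <- function(x) {
    res <- gw_objective(x[1], x[2], config)
    validation <<- c(validation, res$validation)
    res$training
  }
  set.seed(config$seed)
  res <- minimize_gp(fn, lower, upper, n_calls = n_calls)
  trace <- data.frame(call = seq_len(nrow(res$trace)),
                      occupancy = res$trace$x1, puu = res$trace$x2,
                      training = res$trace$value, validation = validation,
                      best_so_far = res$trace$best_so_far)
  list(occupancy = res$par[1], puu = res$par[2], value = res$value,
       trace = trace)
}

## ---------------------------------------------------------------------------
## (mu, lambda) evolution strategy with islands

#' Genetic-algorithm configuration
#'
#' Defaults follow the reference mainland/island setup; scaled-down problems
#' override them.
#'
#' @param mu Population size (mainland).
#' @param lambda Offspring per generation (mainland); `lambda >= mu`.
#' @param mutation_sd SD of the clamped Gaussian gene mutation.
#' @param cx_prob Probability that an offspring pair is produced by
#'   two-point crossover (otherwise the parents are copied before mutation).
#' @param max_generations Generation cap per evolution stage.
#' @param improvement_window,improvement_threshold Stop when the best
#'   fitness improved by less than `improvement_threshold` (relative) over
#'   the last `improvement_window` generations.
#' @param variability_floor Stop when the mean per-gene SD of the population
#'   falls below this.
#' @param n_islands Number of islands per cycle (0 disables the island
#'   phase). One island replaces weak alleles instead of masking.
#' @param island_mu,island_lambda Island population sizes.
#' @param mask_mean,mask_sd The number of consecutive masked barriers per
#'   island is `round(rnorm(mask_mean, mask_sd))`, clamped to \[1, N\].
#' @param weak_threshold Occupancy below which alleles count as weak
#'   barriers on the weak-replacement island.
#' @param n_cycles Mainland/island alternation cycles.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(mu = 256, lambda = 512, mutation_sd = 0.1,
                      cx_prob = 0.6, max_generations = 1000,
                      improvement_window = 25, improvement_threshold = 0.01,
                      variability_floor = 1e-3, n_islands = 3,
                      island_mu = 128, island_lambda = 256,
                      mask_mean = 25, mask_sd = 5, weak_threshold = 0.5,
                      n_cycles = 1) {
  stopifnot(lambda >= mu, mu >= 2)
  structure(as.list(environment()), class = "ga_config")
}

new_individual <- function(n_genes) {
  list(occupancy = runif(n_genes), puu = runif(n_genes))
}

#' Clamped Gaussian mutation
#'
#' Adds independent normal offsets (mean 0, given sd) to every unmasked gene
#' of both vectors, clamping to \[0, 1\].
#'
#' @param ind Individual: list with `occupancy` and `puu` vectors.
#' @param sd Mutation standard deviation.
#' @param mask Optional logical vector: `TRUE` genes are left untouched.
#' @return Mutated individual.
#' @export
mutate <- function(ind, sd, mask = NULL) {
  stopifnot(sd >= 0)
  n <- length(ind$occupancy)
  keep <- if (is.null(mask)) rep(FALSE, n) else mask
  occ <- pmin(pmax(ind$occupancy + rnorm(n, 0, sd), 0), 1)
  puu <- pmin(pmax(ind$puu + rnorm(n, 0, sd), 0), 1)
  occ[keep] <- ind$occupancy[keep]
  puu[keep] <- ind$puu[keep]
  list(occupancy = occ, puu = puu)
}

#' Two-point crossover
#'
#' Two cut points are drawn uniformly on the concatenated genotype
#' (occupancies followed by P_UU values); the segment between them is
#' swapped between the parents.
#'
#' @param p1,p2 Parent individuals with equal gene counts.
#' @return list of two offspring.
#' @export
mate <- function(p1, p2) {
  n <- length(p1$occupancy)
  stopifnot(length(p2$occupancy) == n)
  g1 <- c(p1$occupancy, p1$puu)
  g2 <- c(p2$occupancy, p2$puu)
  cuts <- sort(sample.int(2 * n + 1, 2) - 1L)
  seg <- if (cuts[1] < cuts[2]) (cuts[1] + 1L):cuts[2] else integer(0)
  tmp <- g1[seg]
  g1[seg] <- g2[seg]
  g2[seg] <- tmp
  list(list(occupancy = g1[1:n], puu = g1[(n + 1):(2 * n)]),
       list(occupancy = g2[1:n], puu = g2[(n + 1):(2 * n)]))
}

# One (mu, lambda) evolution stage. fitness_fn(ind, active) -> scalar
# (minimized); `active` marks barriers that participate in the simulation.
# Masked genes are frozen and their barriers inactive.
evolve <- function(pop, fitness_fn, cfg, mu, lambda, mask = NULL,
                   active = NULL, max_generations = cfg$max_generations) {
  n <- length(pop[[1]]$occupancy)
  if (is.null(active)) active <- rep(TRUE, n)
  fits <- vapply(pop, fitness_fn, numeric(1), active = active)
  best_hist <- min(fits)
  history <- data.frame(generation = 0, best = min(fits), mean = mean(fits))
  gen <- 0
  repeat {
    gen <- gen + 1
    offspring <- vector("list", lambda)
    i <- 1
    while (i <= lambda) {
      pa <- pop[[sample.int(length(pop), 1)]]
      pb <- pop[[sample.int(length(pop), 1)]]
      if (runif(1) < cfg$cx_prob) {
        ch <- mate(pa, pb)
      } else {
        ch <- list(pa, pb)
      }
      for (c1 in ch) {
        if (i > lambda) break
        offspring[[i]] <- mutate(c1, cfg$mutation_sd, mask)
        i <- i + 1
      }
    }
    ofits <- vapply(offspring, fitness_fn, numeric(1), active = active)
    keep <- order(ofits)[seq_len(mu)]  # stable: order() breaks ties by index
    pop <- offspring[keep]
    fits <- ofits[keep]
    best_hist <- c(best_hist, min(fits))
    history <- rbind(history, data.frame(generation = gen, best = min(fits),
                                         mean = mean(fits)))
    if (gen >= max_generations) break
    w <- cfg$improvement_window
    if (length(best_hist) > w) {
      prev <- best_hist[length(best_hist) - w]
      if (prev - min(fits) < cfg$improvement_threshold * max(abs(prev), 1e-12))
        break
    }
    gvar <- mean(c(apply(do.call(rbind, lapply(pop, `[[`, "occupancy")), 2, sd),
                   apply(do.call(rbind, lapply(pop, `[[`, "puu")), 2, sd)))
    if (gvar < cfg$variability_floor) break
  }
  list(pop = pop, fits = fits, history = history)
}

#' Per-barrier parameter optimization by a (mu, lambda) evolution strategy
#'
#' Mainland evolution with truncation selection of the top `mu` offspring,
#' followed (optionally) by an island phase: each island starts from the
#' fittest mainland individuals with a random stretch of `k ~ round(N(25,
#' 5))` consecutive barriers masked (inactive, frozen), except one island
#' that instead replaces all weak alleles (occupancy < 0.5) with
#' `(occupancy = 0, P_UU = 1)` and keeps all loci mutable. After the islands
#' converge, half of the mainland is replaced by fitness-proportionate
#' sampling from the island populations and mainland evolution resumes.
#'
#' @param fitness_fn `function(ind, active)` returning the scalar fitness to
#'   minimize; `active` is a logical vector marking barriers that take part
#'   in the simulation (masked barriers are inactive).
#' @param n_genes Number of barriers N.
#' @param cfg A [ga_config()].
#' @param init_pop Optional initial population (defaults to `mu` uniform
#'   random individuals).
#' @return list with `best` (individual), `fitness`, `history`
#'   (per-generation best/mean for every stage), `pop`.
#' @export
run_ga <- function(fitness_fn, n_genes, cfg = ga_config(), init_pop = NULL) {
  pop <- if (is.null(init_pop))
    lapply(seq_len(cfg$mu), function(i) new_individual(n_genes))
  else init_pop
  stage <- evolve(pop, fitness_fn, cfg, cfg$mu, cfg$lambda)
  history <- list(cbind(stage = "mainland-1", stage$history))
  best <- stage$pop[[which.min(stage$fits)]]
  best_fit <- min(stage$fits)

  if (cfg$n_islands > 0) {
    for (cycle in seq_len(cfg$n_cycles)) {
      elite <- stage$pop[order(stage$fits)[seq_len(min(cfg$island_mu,
                                                       length(stage$pop)))]]
      island_pool <- list()
      island_fits <- numeric(0)
      for (isl in seq_len(cfg$n_islands)) {
        ipop <- elite[sample.int(length(elite), cfg$island_mu, replace = TRUE)]
        mask <- NULL
        active <- rep(TRUE, n_genes)
        if (isl < cfg$n_islands || cfg$n_islands == 1) {
          k <- max(1, min(n_genes, round(rnorm(1, cfg$mask_mean, cfg$mask_sd))))
          if (k > n_genes) k <- n_genes
          start <- sample.int(n_genes - k + 1, 1)
          mask <- rep(FALSE, n_genes)
          mask[start:(start + k - 1)] <- TRUE
          active <- !mask
        } else {
          # weak-barrier island: drop weak alleles, keep all loci mutable
          ipop <- lapply(ipop, function(ind) {
            weak <- ind$occupancy < cfg$weak_threshold
            ind$occupancy[weak] <- 0
            ind$puu[weak] <- 1
            ind
          })
        }
        iastage <- evolve(ipop, fitness_fn, cfg, cfg$island_mu,
                          cfg$island_lambda, mask = mask, active = active)
        history[[length(history) + 1L]] <-
          cbind(stage = sprintf("island-%d-%d", cycle, isl), iastage$history)
        island_pool <- c(island_pool, iastage$pop)
        island_fits <- c(island_fits, iastage$fits)
      }
      # fitness-proportionate migration back to the mainland
      w <- 1 / (island_fits + 1e-9)
      n_repl <- floor(cfg$mu / 2)
      migrants <- island_pool[sample.int(length(island_pool), n_repl,
                                         replace = TRUE, prob = w)]
      keep <- stage$pop[order(stage$fits)[seq_len(cfg$mu - n_repl)]]
      stage <- evolve(c(keep, migrants), fitness_fn, cfg, cfg$mu, cfg$lambda)
      history[[length(history) + 1L]] <-
        cbind(stage = sprintf("mainland-%d", cycle + 1), stage$history)
      if (min(stage$fits) < best_fit) {
        best_fit <- min(stage$fits)
        best <- stage$pop[[which.min(stage$fits)]]
      }
    }
  }
  if (min(stage$fits) < best_fit) {
    best_fit <- min(stage$fits)
    best <- stage$pop[[which.min(stage$fits)]]
  }
  list(best = best, fitness = best_fit,
       history = do.call(rbind, history), pop = stage$pop)
}

#' Simulation-backed fitness for per-barrier optimization
#'
#' Builds the `fitness_fn` consumed by [run_ga()]: for an individual's
#' per-barrier (occupancy, P_UU) vectors, simulate the region (fixed seed,
#' so fitness is deterministic given the genes), transform and discretize,
#' and score each barrier as `s = f * p(occupancy)` where `f` is the mean
#' stripe-end mismatch over the rows and columns within
#' `score_window_bins` of the barrier bin and `p` the [penalty()]. The
#' fitness is the mean of `s` over active barriers. Infeasible
#' (occupancy, P_UU) genes are clamped (`P_BB = 0`).
#'
#' @param chroms Chromosome data.frame for the optimized region.
#' @param barriers Barrier annotation (positions/directions fixed; occupancy
#'   and P_UU come from the genotype).
#' @param reference Named list of reference [banded_matrix()] objects.
#' @param config A [sim_config()] for candidate simulations.
#' @param sigma1,sigma2,ref_threshold,sim_threshold Transform settings.
#' @param score_window_bins Half-width (bins) of the per-barrier scoring
#'   window.
#' @param seed Simulation seed reused by every fitness evaluation.
#' @return `function(ind, active)` suitable for [run_ga()].
#' @export
ga_fitness <- function(chroms, barriers, reference,
                       config = sim_config(), sigma1 = 1.0, sigma2 = 1.6,
                       ref_threshold = 0.75, sim_threshold = 0.75,
                       score_window_bins = 10, seed = 0) {
  ref_bands <- lapply(chroms$name, function(cn)
    discretize(dog_transform(band_image(reference[[cn]]), sigma1, sigma2),
               ref_threshold))
  names(ref_bands) <- chroms$name
  bin_size <- config$bin_size
  function(ind, active = rep(TRUE, nrow(barriers))) {
    b <- barriers
    b$occupancy <- ifelse(active, ind$occupancy, 0)
    b$puu <- ind$puu
    b$pbb <- NULL
    cfg <- config
    cfg$seed <- seed
    sim <- run_simulation(chroms, b, cfg, clamp_infeasible = TRUE)
    s_vals <- numeric(0)
    for (cn in chroms$name) {
      sel <- which(b$chrom == cn & active)
      if (length(sel) == 0) next
      tb <- discretize(dog_transform(band_image(sim$matrices[[cn]]),
                                     sigma1, sigma2), sim_threshold)
      sc <- score_matrices(ref_bands[[cn]], tb, mode = "dissimilarity")
      nbins <- length(sc$rows)
      for (j in sel) {
        bin <- floor(b$pos[j] / bin_size)
        win <- max(0, bin - score_window_bins):min(nbins - 1,
                                                   bin + score_window_bins)
        f <- mean(c(sc$rows[win + 1], sc$cols[win + 1]), na.rm = TRUE)
        s_vals <- c(s_vals, f * penalty(ind$occupancy[j]))
      }
    }
    if (length(s_vals) == 0) return(2)  # all barriers masked: worst fitness
    mean(s_vals)
  }
}
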