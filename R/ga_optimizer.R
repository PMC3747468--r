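# Binary-encoded genetic algorithm maximizing the weighted-sum fitness of
# the two normalized larger-is-better screw objectives.

BITS_PER_VAR <- 7L
CHROMOSOME_BITS <- 42L

#' Genetic algorithm configuration
#'
#' Defaults follow the study settings: population 40, crossover rate 90%,
#' per-bit mutation rate 1%. Termination adds a deterministic budget: stop
#' when the elitist best fitness has improved by less than `convergence_tol`
#' over `convergence_window` consecutive generations, or at
#' `max_generations` (the study observed convergence after ~300
#' generations).
#'
#' @param population_size Number of chromosomes per generation.
#' @param crossover_rate Probability that a parent pair undergoes
#'   single-point crossover.
#' @param mutation_rate Independent per-bit flip probability.
#' @param weight Aggregation weight `w` in `[0, 1]` of the bending objective.
#' @param max_generations Hard generation budget.
#' @param convergence_window,convergence_tol Convergence test on the best
#'   fitness trace.
#' @param seed Integer RNG seed.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 40L, crossover_rate = 0.90,
                      mutation_rate = 0.01, weight = 0.5,
                      max_generations = 1000L, convergence_window = 50L,
                      convergence_tol = 1e-4, seed = 1L) {
  stopifnot(weight >= 0, weight <= 1, population_size >= 2L)
  structure(list(population_size = as.integer(population_size),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate, weight = weight,
                 max_generations = as.integer(max_generations),
                 convergence_window = as.integer(convergence_window),
                 convergence_tol = convergence_tol, seed = as.integer(seed)),
            class = "ga_config")
}

#' Decode chromosomes into screw designs
#'
#' A chromosome is 42 bits: six 7-bit fields in canonical variable order.
#' Each field, read most-significant-bit first as an integer `k` in
#' `[0, 127]`, maps linearly onto its variable's range:
#' `value = lower + k/127 * (upper - lower)`. Every chromosome therefore
#' decodes inside the design box.
#'
#' @param bits A logical/integer vector of length 42, or an n x 42 matrix of
#'   chromosomes (one per row).
#' @param space A [design_space()].
#' @return An n x 6 design matrix in physical units.
#' @export
decode <- function(bits, space = design_space()) {
  if (is.null(dim(bits))) bits <- matrix(bits, nrow = 1L)
  if (ncol(bits) != CHROMOSOME_BITS) {
    stop("chromosome must have ", CHROMOSOME_BITS, " bits")
  }
  storage.mode(bits) <- "double"
  pw <- 2^((BITS_PER_VAR - 1L):0L)
  out <- matrix(NA_real_, nrow(bits), 6L, dimnames = list(NULL, SCREW_VARS))
  for (j in seq_len(6L)) {
    k <- bits[, (j - 1L) * BITS_PER_VAR + seq_len(BITS_PER_VAR), drop = FALSE] %*% pw
    v <- SCREW_VARS[j]
    out[, j] <- space$lower[[v]] + drop(k) / 127 * (space$upper[[v]] - space$lower[[v]])
  }
  out
}

#' Fitness context: surrogates plus frozen objective normalization
#'
#' Wraps the two response predictors and the normalization references that
#' turn raw responses into the larger-is-better objectives
#' `F_bending = (MTS_max - MTS) / (MTS_max - MTS_min)` and
#' `F_pullout = (TRF - TRF_min) / (TRF_max - TRF_min)`, clipped to `[0, 1]`.
#' The references are the predictors' min/max over a seeded uniform sample
#' of the design box, computed once and frozen, so objective values are
#' comparable across all weights of a Pareto sweep.
#'
#' @param bending,pullout Either trained [surrogate_net][init_network()]
#'   objects or functions mapping an n x 6 design matrix to a response
#'   vector (MPa / N).
#' @param space A [design_space()].
#' @param n_ref Size of the frozen normalization sample.
#' @param ref_seed Seed for the normalization sample.
#' @return A list of class `fitness_context` with elements
#'   `predict_bending`, `predict_pullout`, `mts_range`, `trf_range`,
#'   `space`.
#' @export
fitness_context <- function(bending, pullout, space = design_space(),
                            n_ref = 100000L, ref_seed = 20130731L) {
  as_pred <- function(obj) {
    if (inherits(obj, "surrogate_net")) {
      # no bound check: GA decodes in-box by construction, and reference
      # screws are deliberately scored by extrapolation
      function(x) predict_physical(obj, x, space, check = FALSE)
    } else if (is.function(obj)) {
      obj
    } else {
      stop("predictor must be a surrogate_net or a function")
    }
  }
  pb <- as_pred(bending)
  pp <- as_pred(pullout)
  set.seed(ref_seed)
  xs <- sapply(SCREW_VARS, function(v) {
    stats::runif(n_ref, space$lower[[v]], space$upper[[v]])
  })
  structure(list(predict_bending = pb, predict_pullout = pp,
                 mts_range = range(pb(xs)), trf_range = range(pp(xs)),
                 space = space),
            class = "fitness_context")
}

#' Normalized larger-is-better objective values
#'
#' @param ctx A [fitness_context()].
#' @param d A design or n x 6 design matrix.
#' @return An n x 2 matrix with columns `f_bending` (high = low bending
#'   stress = long fatigue life) and `f_pullout` (high = strong axial
#'   holding power), both clipped to `[0, 1]`.
#' @export
objective_values <- function(ctx, d) {
  x <- as_design_matrix(d)
  clip01 <- function(z) pmin(pmax(z, 0), 1)
  fb <- clip01((ctx$mts_range[2] - ctx$predict_bending(x)) / diff(ctx$mts_range))
  fp <- clip01((ctx$predict_pullout(x) - ctx$trf_range[1]) / diff(ctx$trf_range))
  cbind(f_bending = fb, f_pullout = fp)
}

#' Weighted-sum fitness of chromosomes
#'
#' `F = w * F_bending + (1 - w) * F_pullout` for feasible designs;
#' chromosomes decoding to a constraint-violating design receive fitness 0
#' (death penalty).
#'
#' @param bits A chromosome or n x 42 matrix of chromosomes.
#' @param ctx A [fitness_context()].
#' @param w Aggregation weight in `[0, 1]`.
#' @return Numeric fitness vector in `[0, 1]`.
#' @export
ga_fitness <- function(bits, ctx, w) {
  stopifnot(w >= 0, w <= 1)
  d <- decode(bits, ctx$space)
  f <- objective_values(ctx, d)
  fit <- unname(w * f[, "f_bending"] + (1 - w) * f[, "f_pullout"])
  fit[!check_constraints(d, ctx$space)$pass] <- 0
  fit
}

#' Roulette-wheel (fitness-proportionate) selection
#'
#' Member `i` is drawn with probability `fitness_i / sum(fitness)`; if all
#' fitnesses are zero the draw is uniform. Uses the current R RNG state.
#'
#' @param fitnesses Nonnegative fitness vector.
#' @param n Number of draws (with replacement).
#' @return Integer vector of selected indices.
#' @export
roulette_select <- function(fitnesses, n = 1L) {
  stopifnot(all(fitnesses >= 0))
  if (sum(fitnesses) == 0) {
    sample.int(length(fitnesses), n, replace = TRUE)
  } else {
    sample.int(length(fitnesses), n, replace = TRUE, prob = fitnesses)
  }
}

#' Single-point crossover
#'
#' With probability `rate`, a cut point is drawn uniformly between bit 1 and
#' bit 41 and the tails are exchanged; otherwise the offspring are copies.
#' The two offspring always conserve the parents' combined multiset of bits.
#'
#' @param a,b Parent chromosomes (length 42).
#' @param rate Crossover probability.
#' @return A list of two offspring chromosomes.
#' @export
crossover <- function(a, b, rate) {
  stopifnot(length(a) == CHROMOSOME_BITS, length(b) == CHROMOSOME_BITS)
  if (stats::runif(1) < rate) {
    cut <- sample.int(CHROMOSOME_BITS - 1L, 1L)
    list(c(a[1:cut], b[(cut + 1L):CHROMOSOME_BITS]),
         c(b[1:cut], a[(cut + 1L):CHROMOSOME_BITS]))
  } else {
    list(a, b)
  }
}

#' Bit-flip mutation
#'
#' Each bit is flipped independently with probability `rate`.
#'
#' @param bits A chromosome (length 42).
#' @param rate Per-bit mutation probability.
#' @return The mutated chromosome.
#' @export
mutate <- function(bits, rate) {
  flip <- stats::runif(length(bits)) < rate
  bits[flip] <- 1 - bits[flip]
  bits
}

#' Run the genetic algorithm at one aggregation weight
#'
#' Generational GA with roulette selection, single-point crossover, bit-flip
#' mutation, and one elite copied unchanged into the next generation (which
#' makes the elitist best-fitness trace non-decreasing and the convergence
#' criterion well defined). Terminates when the best fitness has improved by
#' less than `cfg$convergence_tol` over `cfg$convergence_window` consecutive
#' generations, or at `cfg$max_generations`.
#'
#' @param ctx A [fitness_context()].
#' @param cfg A [ga_config()].
#' @return List with `best_design` (named vector), `best_fitness`,
#'   `best_objectives` (f_bending, f_pullout), `generations` (count run),
#'   `converged`, and `trace`: a data frame with one row per generation
#'   (best fitness, decoded best design, its objective values).
#' @export
run_ga <- function(ctx, cfg = ga_config()) {
  set.seed(cfg$seed)
  np <- cfg$population_size
  pop <- matrix(as.numeric(stats::runif(np * CHROMOSOME_BITS) < 0.5),
                nrow = np, ncol = CHROMOSOME_BITS)

  best_bits <- NULL
  best_fit <- -Inf
  trace_fit <- numeric(0)
  trace_design <- NULL
  converged <- FALSE

  for (gen in seq_len(cfg$max_generations)) {
    fit <- ga_fitness(pop, ctx, cfg$weight)
    i <- which.max(fit)
    if (fit[i] > best_fit) {
      best_fit <- fit[i]
      best_bits <- pop[i, ]
    }
    trace_fit[gen] <- best_fit
    trace_design <- rbind(trace_design, decode(best_bits, ctx$space))

    if (gen > cfg$convergence_window) {
      if (trace_fit[gen] - trace_fit[gen - cfg$convergence_window] <
          cfg$convergence_tol) {
        converged <- TRUE
        break
      }
    }
    if (gen == cfg$max_generations) break

    # next generation: 1 elite + offspring from roulette-selected pairs
    n_off <- np - 1L
    parents <- roulette_select(fit, 2L * ceiling(n_off / 2))
    children <- vector("list", length(parents))
    for (k in seq_len(length(parents) / 2)) {
      off <- crossover(pop[parents[2L * k - 1L], ], pop[parents[2L * k], ],
                       cfg$crossover_rate)
      children[[2L * k - 1L]] <- mutate(off[[1L]], cfg$mutation_rate)
      children[[2L * k]] <- mutate(off[[2L]], cfg$mutation_rate)
    }
    pop <- rbind(best_bits, do.call(rbind, children[seq_len(n_off)]))
  }

  if (best_fit <= 0 && cfg$weight > 0 && cfg$weight < 1) {
    stop("genetic algorithm never found a feasible design with positive fitness")
  }
  bd <- decode(best_bits, ctx$space)
  bo <- objective_values(ctx, bd)
  trace_obj <- objective_values(ctx, trace_design)
  trace <- data.frame(generation = seq_along(trace_fit),
                      best_fitness = trace_fit, trace_design, trace_obj)
  list(best_design = bd[1L, ], best_fitness = best_fit,
       best_objectives = bo[1L, ], generations = length(trace_fit),
       converged = converged, trace = trace)
}
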