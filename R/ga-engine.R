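# Genetic algorithm jointly optimizing SVM hyperparameters and a binary
# feature mask.  A chromosome concatenates 32-bit parameter genes (C, gamma,
# optionally epsilon) with a 0/1 mask over the current feature space; the
# fitness of a chromosome is the 10-fold cross-validated accuracy of the SVM
# it decodes to.  Evolution uses roulette-wheel selection, single-point
# crossover and per-bit mutation.

GMAX <- 2^32 - 1
PARAM_BITS <- 32L

#' GA configuration
#'
#' Defaults follow the classical small-population setup for wrapper feature
#' selection: population 5, crossover rate 0.8, per-bit mutation rate 0.01,
#' 10-fold CV fitness.  Parameter genes map the 32-bit integer linearly onto
#' an interval; by default that interval is `[log C_min, log C_max]` (and
#' likewise for gamma) with libsvm-style bounds `C` in `[2^-5, 2^15]` and
#' `gamma` in `[2^-15, 2^3]`, because the viable region of both
#' hyperparameters spans orders of magnitude and a linear mapping
#' concentrates nearly all of the code space in the top decade, starving
#' the search.  `decode_scale = "linear"` decodes directly onto
#' `[min, max]`.
#'
#' @param population_size Number of chromosomes per generation (>= 2).
#' @param crossover_rate Probability a parent pair is recombined.
#' @param mutation_rate Per-bit flip probability.
#' @param c_bounds,gamma_bounds Length-2 increasing numeric search
#'   intervals for C and gamma.
#' @param epsilon_bounds Optional interval for an epsilon gene; when given,
#'   chromosomes carry a third 32-bit gene that is decoded but not used by
#'   the C-classifier.
#' @param k_folds CV folds for the fitness (default 10).
#' @param max_generations Generation budget (0 = score the initial
#'   population only).
#' @param target_fitness Early-stopping fitness level in `[0, 1]`.
#' @param seed Integer seed; the whole run is deterministic given it.
#' @param elitism Copy the best individual unchanged into the next
#'   generation (default `FALSE`).
#' @param decode_scale `"linear"` (default) or `"log"` parameter decoding.
#' @return A validated `ga_config` list.
#' @export
ga_config <- function(population_size = 5, crossover_rate = 0.8,
                      mutation_rate = 0.01, c_bounds = c(2^-5, 2^15),
                      gamma_bounds = c(2^-15, 2^3), epsilon_bounds = NULL,
                      k_folds = 10, max_generations = 30,
                      target_fitness = 1.0, seed = 1, elitism = FALSE,
                      decode_scale = c("log", "linear")) {
  decode_scale <- match.arg(decode_scale)
  cfg <- list(
    population_size = assert_count(population_size, "population_size", min = 2L),
    crossover_rate = assert_scalar_number(crossover_rate, "crossover_rate", 0, 1),
    mutation_rate = assert_scalar_number(mutation_rate, "mutation_rate", 0, 1),
    c_bounds = c_bounds,
    gamma_bounds = gamma_bounds,
    epsilon_bounds = epsilon_bounds,
    k_folds = assert_count(k_folds, "k_folds", min = 2L),
    max_generations = assert_count(max_generations, "max_generations", min = 0L),
    target_fitness = assert_scalar_number(target_fitness, "target_fitness", 0, 1),
    seed = assert_count(seed, "seed"),
    elitism = isTRUE(elitism),
    decode_scale = decode_scale
  )
  for (nm in c("c_bounds", "gamma_bounds", "epsilon_bounds")) {
    b <- cfg[[nm]]
    if (is.null(b) && nm == "epsilon_bounds") next
    if (!is.numeric(b) || length(b) != 2L || b[1L] >= b[2L]) {
      stop(sprintf("'%s' must be an increasing (min, max) pair", nm),
           call. = FALSE)
    }
    if (cfg$decode_scale == "log" && b[1L] <= 0) {
      stop(sprintf("'%s' must be positive for log-scale decoding", nm),
           call. = FALSE)
    }
  }
  cfg$n_params <- if (is.null(cfg$epsilon_bounds)) 2L else 3L
  class(cfg) <- "ga_config"
  cfg
}

n_param_bits <- function(config) PARAM_BITS * config$n_params

#' Construct a chromosome from a raw bit vector
#'
#' @param bits Integer 0/1 vector: `32 * n_params` parameter bits followed
#'   by one mask bit per feature.
#' @param n_params Number of 32-bit parameter genes (2 or 3).
#' @return A `chromosome` list with `bits` and `n_params`.
#' @export
chromosome <- function(bits, n_params = 2L) {
  bits <- as.integer(bits)
  if (!all(bits %in% c(0L, 1L))) stop("bits must be 0/1", call. = FALSE)
  if (length(bits) <= PARAM_BITS * n_params) {
    stop("chromosome must carry at least one feature bit", call. = FALSE)
  }
  structure(list(bits = bits, n_params = as.integer(n_params)),
            class = "chromosome")
}

feature_mask <- function(chrom) {
  chrom$bits[-seq_len(PARAM_BITS * chrom$n_params)]
}

param_gene <- function(chrom, i) {
  chrom$bits[(i - 1L) * PARAM_BITS + seq_len(PARAM_BITS)]
}

# replace the feature-mask section of a chromosome
`feature_mask<-` <- function(chrom, value) {
  chrom$bits[-seq_len(PARAM_BITS * chrom$n_params)] <- as.integer(value)
  chrom
}

#' Decode a 32-bit parameter gene onto an interval
#'
#' With `B = sum_i bit_i 2^(i-1)` and `g_max = 2^32 - 1`, the decoded value
#' is `lo + (B / g_max) (hi - lo)`; both endpoints are attained exactly at
#' the all-zero and all-one genes, and the map is monotone in B.
#'
#' @param bits Integer 0/1 vector of length 32, bit i weighted `2^(i-1)`.
#' @param lo,hi Interval bounds, `lo < hi`.
#' @param scale `"linear"` (default) decodes on `[lo, hi]` directly;
#'   `"log"` decodes on `[log lo, log hi]` and exponentiates.
#' @return A number in `[lo, hi]`.
#' @export
decode_parameter <- function(bits, lo, hi, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  if (length(bits) != PARAM_BITS) {
    stop("parameter gene must have exactly 32 bits", call. = FALSE)
  }
  if (!(lo < hi)) stop("'lo' must be < 'hi'", call. = FALSE)
  b <- sum(as.numeric(bits) * 2^(seq_len(PARAM_BITS) - 1))
  if (b == 0) return(lo)
  if (b == GMAX) return(hi)
  if (scale == "log") {
    exp(log(lo) + (b / GMAX) * (log(hi) - log(lo)))
  } else {
    lo + (b / GMAX) * (hi - lo)
  }
}

#' Encode a parameter value back into a 32-bit gene
#'
#' Inverse of [decode_parameter()] up to quantization: the nearest-integer
#' `B = round(g_max (v - lo) / (hi - lo))` expressed in 32 bits.
#'
#' @param value Number in `[lo, hi]`.
#' @inheritParams decode_parameter
#' @return Integer 0/1 vector of length 32.
#' @export
encode_parameter <- function(value, lo, hi, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  if (scale == "log") {
    return(encode_parameter(log(value), log(lo), log(hi)))
  }
  b <- round(GMAX * (value - lo) / (hi - lo))
  b <- min(max(b, 0), GMAX)
  bits <- integer(PARAM_BITS)
  for (i in seq_len(PARAM_BITS)) {
    bits[i] <- as.integer(b %% 2)
    b <- b %/% 2
  }
  bits
}

#' Decode a chromosome into SVM parameters and a feature subset
#'
#' @param chrom A [chromosome()].
#' @param config A [ga_config()] providing the parameter bounds.
#' @param probe_ids Ordered feature IDs the mask refers to.
#' @return A list with `params` ([svm_params()]) and `selected` (probe IDs
#'   with mask bit 1, order preserved).
#' @export
decode_chromosome <- function(chrom, config, probe_ids) {
  mask <- feature_mask(chrom)
  if (length(mask) != length(probe_ids)) {
    stop("chromosome mask length does not match the feature space",
         call. = FALSE)
  }
  if (chrom$n_params != config$n_params) {
    stop("chromosome and config disagree on the number of parameter genes",
         call. = FALSE)
  }
  C <- decode_parameter(param_gene(chrom, 1L), config$c_bounds[1L],
                        config$c_bounds[2L], config$decode_scale)
  gamma <- decode_parameter(param_gene(chrom, 2L), config$gamma_bounds[1L],
                            config$gamma_bounds[2L], config$decode_scale)
  eps <- if (config$n_params == 3L) {
    decode_parameter(param_gene(chrom, 3L), config$epsilon_bounds[1L],
                     config$epsilon_bounds[2L], config$decode_scale)
  } else 0
  list(params = svm_params(C, gamma, eps), selected = probe_ids[mask == 1L])
}

# an all-zero mask decodes to an SVM with no features, which is undefined;
# repair by setting one random bit with the run RNG
repair_mask <- function(chrom) {
  mask <- feature_mask(chrom)
  if (!any(mask == 1L)) {
    mask[sample.int(length(mask), 1L)] <- 1L
    feature_mask(chrom) <- mask
  }
  chrom
}

random_chromosome <- function(n_features, config) {
  total <- n_param_bits(config) + n_features
  repair_mask(chromosome(stats::rbinom(total, 1L, 0.5), config$n_params))
}

#' Fitness of a chromosome: cross-validated SVM accuracy
#'
#' Decodes the chromosome, restricts the training matrix to its selected
#' features and returns the stratified k-fold CV accuracy under the decoded
#' hyperparameters.  The fold seed is derived from `config$seed`, so every
#' chromosome in a run is scored on the same folds.  When a memoization
#' environment is supplied, identical bit strings are scored once.
#'
#' @param chrom A [chromosome()].
#' @param x Training expression matrix (probes x samples).
#' @param y Training labels.
#' @param config A [ga_config()].
#' @param cache Optional environment used as a fitness memo.
#' @return Fitness in `[0, 1]`.
#' @export
evaluate_fitness <- function(chrom, x, y, config, cache = NULL) {
  key <- if (!is.null(cache)) paste(chrom$bits, collapse = "") else NULL
  if (!is.null(key) && !is.null(cache[[key]])) return(cache[[key]])
  dec <- decode_chromosome(chrom, config, rownames(x))
  fit <- cross_val_accuracy(x[dec$selected, , drop = FALSE], y, dec$params,
                            k = config$k_folds,
                            seed = derive_seed(config$seed, "cv"))
  if (!is.null(key)) cache[[key]] <- fit
  fit
}

#' Roulette-wheel selection
#'
#' Returns index j with probability `f_j / sum(f)`; when all fitnesses are
#' zero the draw is uniform.  Uses the current RNG stream.
#'
#' @param fitnesses Nonnegative numeric vector.
#' @return A single index.
#' @export
roulette_select <- function(fitnesses) {
  if (any(fitnesses < 0)) stop("fitness values must be >= 0", call. = FALSE)
  s <- sum(fitnesses)
  if (s == 0) return(sample.int(length(fitnesses), 1L))
  sample.int(length(fitnesses), 1L, prob = fitnesses / s)
}

#' Single-point crossover
#'
#' With probability `rate` a cut point is drawn uniformly from positions
#' 1..L-1 and the tails of the two parents are swapped; otherwise the
#' children are copies.  Children with an emptied mask are repaired.
#'
#' @param parent1,parent2 Chromosomes of equal length.
#' @param rate Crossover probability.
#' @return A list of two child chromosomes.
#' @export
single_point_crossover <- function(parent1, parent2, rate) {
  if (length(parent1$bits) != length(parent2$bits)) {
    stop("parents must have equal length", call. = FALSE)
  }
  c1 <- parent1
  c2 <- parent2
  if (stats::runif(1L) < rate) {
    L <- length(parent1$bits)
    cut <- sample.int(L - 1L, 1L)
    tail_idx <- (cut + 1L):L
    c1$bits[tail_idx] <- parent2$bits[tail_idx]
    c2$bits[tail_idx] <- parent1$bits[tail_idx]
  }
  list(repair_mask(c1), repair_mask(c2))
}

#' Per-bit mutation
#'
#' Each bit flips independently with probability `rate`; an emptied feature
#' mask is repaired with one random set bit.
#'
#' @param chrom A [chromosome()].
#' @param rate Per-bit flip probability in `[0, 1]`.
#' @return The mutated chromosome.
#' @export
mutate <- function(chrom, rate) {
  assert_scalar_number(rate, "rate", 0, 1)
  flip <- stats::runif(length(chrom$bits)) < rate
  chrom$bits[flip] <- 1L - chrom$bits[flip]
  repair_mask(chrom)
}

#' Evolve a population of GA-SVM chromosomes
#'
#' Initializes `population_size` random chromosomes (independent
#' Bernoulli(0.5) bits), scores every generation by CV accuracy, and builds
#' successors by roulette selection of parent pairs, single-point crossover
#' and bit-flip mutation until the fitness target or the generation budget
#' is reached.  The best-so-far chromosome across all generations is
#' returned, so the result never degrades with more generations.
#'
#' @param x Training expression matrix (probes x samples); its rownames are
#'   the feature space the mask ranges over.
#' @param y Training labels.
#' @param config A [ga_config()].
#' @return A list with `best` (chromosome), `best_fitness`, `params`
#'   (decoded [svm_params()]), `selected` (probe IDs), and `history`
#'   (data.frame: `generation`, `best_fitness`, `mean_fitness`,
#'   `best_so_far`, `n_selected_best`).
#' @export
evolve <- function(x, y, config) {
  stopifnot(inherits(config, "ga_config"))
  x <- validate_expression_matrix(x)
  y <- check_labels(x, y)
  G <- nrow(x)
  cache <- new.env(parent = emptyenv())
  with_seed(derive_seed(config$seed, "ga"), {
    pop <- replicate(config$population_size, random_chromosome(G, config),
                     simplify = FALSE)
    best <- NULL
    best_fit <- -Inf
    history <- vector("list", config$max_generations + 1L)
    gen <- 0L
    repeat {
      fits <- vapply(pop, evaluate_fitness, numeric(1L), x = x, y = y,
                     config = config, cache = cache)
      gen_best <- which.max(fits)
      if (fits[gen_best] > best_fit) {
        best_fit <- fits[gen_best]
        best <- pop[[gen_best]]
      }
      history[[gen + 1L]] <- data.frame(
        generation = gen,
        best_fitness = fits[gen_best],
        mean_fitness = mean(fits),
        best_so_far = best_fit,
        n_selected_best = sum(feature_mask(best))
      )
      if (best_fit >= config$target_fitness || gen >= config$max_generations) {
        break
      }
      nxt <- if (config$elitism) list(pop[[gen_best]]) else list()
      while (length(nxt) < config$population_size) {
        p1 <- pop[[roulette_select(fits)]]
        p2 <- pop[[roulette_select(fits)]]
        kids <- single_point_crossover(p1, p2, config$crossover_rate)
        kids <- lapply(kids, mutate, rate = config$mutation_rate)
        nxt <- c(nxt, kids)
      }
      pop <- nxt[seq_len(config$population_size)]
      gen <- gen + 1L
    }
    dec <- decode_chromosome(best, config, rownames(x))
    list(
      best = best,
      best_fitness = best_fit,
      params = dec$params,
      selected = dec$selected,
      history = do.call(rbind, history[!vapply(history, is.null, logical(1L))])
    )
  })
}
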