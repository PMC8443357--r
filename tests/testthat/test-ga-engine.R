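test_that("parameter genes decode linearly with exact interval endpoints", {
  zero <- rep(0L, 32)
  one <- rep(1L, 32)
  expect_identical(decode_parameter(zero, 0.01, 1000), 0.01)
  expect_identical(decode_parameter(one, 0.01, 1000), 1000)
  bit1 <- c(1L, rep(0L, 31))
  expect_equal(decode_parameter(bit1, 0, 1), 1 / (2^32 - 1))
  expect_identical(decode_parameter(zero, 2^-15, 8, scale = "log"), 2^-15)
  expect_identical(decode_parameter(one, 2^-15, 8, scale = "log"), 8)
  expect_error(decode_parameter(rep(0L, 31), 0, 1), "32 bits")
})

test_that("decoding is monotone in the encoded integer and round-trips", {
  set.seed(23)
  for (i in 1:50) {
    bits <- sample(0:1, 32, replace = TRUE)
    b <- sum(bits * 2^(0:31))
    v <- decode_parameter(bits, 0.01, 1000)
    expect_identical(encode_parameter(v, 0.01, 1000), as.integer(bits))
    # bump the low bit: value must not decrease
    if (bits[1] == 0) {
      bits2 <- bits
      bits2[1] <- 1L
      expect_gte(decode_parameter(bits2, 0.01, 1000), v)
    }
  }
})

test_that("chromosomes decode to parameters and a feature subset", {
  cfg <- ga_config(seed = 1)
  bits <- c(rep(0L, 32), rep(1L, 32), 1L, 0L, 1L)
  chrom <- chromosome(bits, n_params = 2)
  dec <- decode_chromosome(chrom, cfg, c("a", "b", "c"))
  expect_identical(dec$selected, c("a", "c"))
  expect_identical(dec$params$C, cfg$c_bounds[1])
  expect_identical(dec$params$gamma, cfg$gamma_bounds[2])
  all_on <- chromosome(c(rep(0L, 64), rep(1L, 3)), 2)
  expect_identical(decode_chromosome(all_on, cfg, c("a", "b", "c"))$selected,
                   c("a", "b", "c"))
  # an epsilon gene is decoded when configured, and ignored by the classifier
  cfg3 <- ga_config(epsilon_bounds = c(0.001, 1), seed = 1)
  chrom3 <- chromosome(rep(c(0L, 1L, 0L, 1L), c(32, 32, 32, 4)), n_params = 3)
  dec3 <- decode_chromosome(chrom3, cfg3, letters[1:4])
  expect_identical(dec3$params$epsilon, 0.001)
})

test_that("roulette selection is fitness-proportional with degenerate fallback", {
  set.seed(11)
  draws <- replicate(10000, roulette_select(c(1, 3)))
  expect_equal(mean(draws == 2), 0.75, tolerance = 0.02)
  uniform <- replicate(10000, roulette_select(c(1, 1, 1, 1)))
  expect_equal(unname(tabulate(uniform, 4) / 10000), rep(0.25, 4),
               tolerance = 0.03)
  zeros <- replicate(2000, roulette_select(c(0, 0)))
  expect_equal(mean(zeros == 1), 0.5, tolerance = 0.05)
  expect_error(roulette_select(c(0.5, -0.1)), ">= 0")
})

test_that("single-point crossover swaps tails and degenerates to copying", {
  p1 <- chromosome(c(rep(0L, 67), 1L), 2)   # mask ends 0001
  p2 <- chromosome(rep(1L, 68), 2)
  set.seed(9)
  kids <- single_point_crossover(p1, p2, rate = 1)
  joint <- kids[[1]]$bits + kids[[2]]$bits  # complementary except repairs
  cut <- which(diff(kids[[1]]$bits) != 0)
  expect_true(all(joint[1:64] == 1))        # param genes swap cleanly
  # children are prefix-of-one + tail-of-other
  n_switch <- sum(diff(kids[[1]]$bits[1:64]) != 0)
  expect_lte(n_switch, 1)

  set.seed(10)
  for (i in 1:20) {
    kids0 <- single_point_crossover(p1, p2, rate = 0)
    expect_identical(kids0[[1]]$bits, p1$bits)
    expect_identical(kids0[[2]]$bits, p2$bits)
  }
  twins <- single_point_crossover(p2, p2, rate = 1)
  expect_identical(twins[[1]]$bits, p2$bits)
  expect_identical(twins[[2]]$bits, p2$bits)
  expect_error(single_point_crossover(p1, chromosome(rep(1L, 70), 2), 1),
               "equal length")
})

test_that("mutation flips bits at the nominal rate and repairs empty masks", {
  chrom <- chromosome(c(rep(0L, 64), rep(1L, 936)), 2)  # 1000 bits
  set.seed(15)
  expect_identical(mutate(chrom, 0)$bits, chrom$bits)
  flipped <- mutate(chrom, 1)
  expect_identical(flipped$bits[1:64], rep(1L, 64))
  expect_equal(sum(flipped$bits[65:1000]), 1)  # complement emptied the mask; repaired
  mean_flips <- mean(replicate(200, sum(mutate(chrom, 0.01)$bits != chrom$bits)))
  expect_equal(mean_flips, 10, tolerance = 3 / 10)  # Binomial(1000, 0.01) mean 10
})

test_that("fitness is the CV accuracy of the decoded model and is memoized", {
  ds <- generate_dataset(synthetic_spec(n_probes = 10, n_informative = 3,
                                        shift_delta = 4, noise_sd = 0.5,
                                        seed = 6))
  cfg <- ga_config(k_folds = 5, seed = 6)
  informative <- which(ds$truth$informative)
  mask <- integer(10)
  mask[informative] <- 1L
  good_bits <- c(encode_parameter(10, cfg$c_bounds[1], cfg$c_bounds[2], "log"),
                 encode_parameter(0.1, cfg$gamma_bounds[1], cfg$gamma_bounds[2], "log"),
                 mask)
  chrom <- chromosome(good_bits, 2)
  cache <- new.env()
  fit <- evaluate_fitness(chrom, ds$x, ds$y, cfg, cache)
  expect_gte(fit, 0.95)
  expect_identical(evaluate_fitness(chrom, ds$x, ds$y, cfg, cache), fit)
  expect_length(ls(cache), 1)
  # equals a direct CV call with the decoded parameters
  dec <- decode_chromosome(chrom, cfg, rownames(ds$x))
  direct <- cross_val_accuracy(ds$x[dec$selected, ], ds$y, dec$params, k = 5,
                               seed = gasvm:::derive_seed(6, "cv"))
  expect_identical(fit, direct)
})

test_that("evolve respects the generation budget and keeps the best-so-far", {
  ds <- generate_dataset(synthetic_spec(n_probes = 8, n_informative = 2,
                                        shift_delta = 3, noise_sd = 0.6,
                                        seed = 18))
  cfg0 <- ga_config(population_size = 4, max_generations = 0, k_folds = 5,
                    seed = 18)
  res0 <- evolve(ds$x, ds$y, cfg0)
  expect_equal(nrow(res0$history), 1)
  expect_equal(res0$history$generation, 0)

  # pure-noise data cannot reach the fitness target, so the full budget runs
  null_ds <- generate_dataset(synthetic_spec(n_probes = 8, n_informative = 0,
                                             seed = 19))
  cfg <- ga_config(population_size = 4, max_generations = 6, k_folds = 5,
                   seed = 18)
  res <- evolve(null_ds$x, null_ds$y, cfg)
  expect_equal(nrow(res$history), 7)
  expect_true(all(diff(res$history$best_so_far) >= 0))
  expect_equal(res$best_fitness, max(res$history$best_fitness))
  expect_true(all(res$selected %in% rownames(null_ds$x)))
  expect_gte(length(res$selected), 1)
})

test_that("a full GA run is deterministic in its seed", {
  ds <- generate_dataset(synthetic_spec(n_probes = 8, n_informative = 2,
                                        shift_delta = 3, noise_sd = 0.6,
                                        seed = 4))
  cfg <- ga_config(population_size = 4, max_generations = 3, k_folds = 5,
                   seed = 44)
  a <- evolve(ds$x, ds$y, cfg)
  b <- evolve(ds$x, ds$y, cfg)
  expect_identical(a$best$bits, b$best$bits)
  expect_identical(a$history, b$history)
  cfg2 <- ga_config(population_size = 4, max_generations = 3, k_folds = 5,
                    seed = 45)
  expect_false(identical(evolve(ds$x, ds$y, cfg2)$history, a$history))
})
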