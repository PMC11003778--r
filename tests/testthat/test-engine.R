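test_that("parent sampling is fitness-weighted within each sex", {
  pop <- make_test_population(
    replicate(10, NULL, simplify = FALSE),
    sex = rep(c("female", "male"), each = 5)
  )
  # uniform weights: maternity counts consistent with equal probabilities
  pop$fitness <- rep(1, 10)
  set.seed(41)
  pairs <- select_parents(pop, n = 10000)
  counts <- tabulate(pairs[, "mother"], nbins = 10)[1:5]
  chi <- sum((counts - 2000)^2 / 2000)
  expect_lt(chi, qchisq(0.999, df = 4))
  expect_true(all(pairs[, "father"] %in% 6:10))

  # degenerate weights: the only fit female mothers every offspring
  pop$fitness <- c(1, 0, 0, 0, 0, rep(1, 5))
  expect_true(all(select_parents(pop, n = 200)[, "mother"] == 1))

  # 2:1 weights give 2:1 maternity in expectation
  pop$fitness <- c(2, 1, 0, 0, 0, rep(1, 5))
  set.seed(42)
  mothers <- select_parents(pop, n = 9000)[, "mother"]
  frac1 <- mean(mothers == 1)
  expect_within_sigma(frac1, 2 / 3, sqrt((2 / 3) * (1 / 3) / 9000))

  # extinction errors: no viable parent in one sex
  pop$fitness <- c(0, 0, 0, 0, 0, rep(1, 5))
  expect_error(select_parents(pop), "female",
               class = "tesim_extinction_error")
  all_female <- make_test_population(list(NULL, NULL),
                                     sex = c("female", "female"))
  all_female$fitness <- c(1, 1)
  expect_error(select_parents(all_female), "male")
})

test_that("transposition duplicates copies at the configured rate", {
  cfg <- tiny_cfg(u = 0.5, chrom_length = 1e6)
  m5 <- cbind(0, c(10, 20, 30, 40, 50), 0)

  # u' = 0 for every copy: genome unchanged
  set.seed(43)
  out <- transpose_genome(m5, tiny_cfg(u = 0, k = 0.2, a = 0.02),
                          M = rep(100L, 5))
  expect_identical(nrow(out), 5L)

  # u' = 1: every copy duplicates exactly once
  cfg1 <- tiny_cfg(u = 1, chrom_length = 1e6)
  out1 <- transpose_genome(m5, cfg1)
  expect_identical(nrow(out1), 10L)
  expect_false(anyDuplicated(paste(out1[, 1], out1[, 2], out1[, 3])) > 0)
  expect_true(all(out1[, 2] >= 0 & out1[, 2] < 1e6))

  # binomial mean: n = 100 copies at u = 0.05 gain 5 on average
  m100 <- cbind(0, seq(10, 1000, by = 10), 0)
  set.seed(44)
  gains <- replicate(1500, nrow(transpose_genome(m100, tiny_cfg(u = 0.05)))) - 100
  expect_within_sigma(mean(gains), 5, sqrt(100 * 0.05 * 0.95 / 1500))

  # k > 0 requires magnitudes; clamped copies never transpose
  expect_error(transpose_genome(m5, tiny_cfg(u = 0.5, k = 0.2, a = 0.02)), "M")
  out_clamp <- transpose_genome(m5, tiny_cfg(u = 0.5, k = 0.2, a = 0.02),
                                M = rep(5L, 5))
  expect_identical(nrow(out_clamp), 5L)
})

test_that("one generation keeps the census and applies lethal selection", {
  cfg <- te_config(N = 40, u = 0, s = 1, r = 0, n0 = 1, chrom_length = 1e5,
                   fitness_mode = "additive", max_generations = 5)
  layouts <- c(replicate(20, cbind(0, sample.int(1e5, 1), 0),
                         simplify = FALSE),
               replicate(20, NULL, simplify = FALSE))
  pop <- make_test_population(layouts,
                              sex = rep(c("female", "male"), 20))
  set.seed(45)
  nxt <- step_generation(pop, cfg)
  expect_identical(population_size(nxt), 40L)  # census conservation
  expect_identical(nxt$generation, 1L)
  # all TE carriers have W = 0, so every offspring descends from TE-free
  # parents and carries no TE
  expect_true(all(copy_number(nxt) == 0L))
})

test_that("neutral dynamics leave the mean copy number drift-free", {
  set.seed(46)
  cfg <- te_config(N = 60, u = 0, s = 0, r = 1e-6, n0 = 4,
                   chrom_length = 1e6, max_generations = 5)
  layouts <- replicate(60, cbind(0, sample.int(1e6, 4), 0), simplify = FALSE)
  pop <- make_test_population(layouts,
                              sex = rep(c("female", "male"), 30))
  deltas <- replicate(300, {
    nxt <- step_generation(pop, cfg)
    mean(copy_number(nxt)) - 4
  })
  expect_within_sigma(mean(deltas), 0, stats::sd(deltas) / sqrt(300))
})

test_that("replicate runs are deterministic under a fixed seed", {
  cfg <- te_config(N = 80, u = 0.05, s = 5e-3, r = 1e-6, n0 = 5,
                   chrom_length = 1e6, max_generations = 80, seed = 47)
  run1 <- run_simulation(cfg)
  run2 <- run_simulation(cfg)
  expect_identical(run1$trajectory, run2$trajectory)
  run3 <- run_simulation(cfg, seed = 48)
  expect_false(identical(run1$trajectory, run3$trajectory))
})

test_that("terminal statuses are detected and reported", {
  # no initial copies: nothing can ever transpose
  cfg0 <- te_config(N = 30, u = 0.1, s = 0, n0 = 0, chrom_length = 1e5,
                    max_generations = 50)
  run0 <- run_simulation(cfg0, seed = 49)
  expect_identical(run0$status, "te_loss")
  expect_identical(nrow(run0$trajectory), 1L)

  # selection several-fold stronger than transposition removes all TEs
  cfg_loss <- te_config(N = 150, u = 0.01, s = 0.08, r = 1e-6, n0 = 10,
                        chrom_length = 1e6, max_generations = 3000)
  run_loss <- run_simulation(cfg_loss, seed = 50)
  expect_identical(run_loss$status, "te_loss")
  expect_equal(tail(run_loss$trajectory$mean_copy_number, 1), 0)

  # transposition far stronger than selection drives fitness to zero
  cfg_crash <- te_config(N = 100, u = 0.1, s = 1e-4, r = 1e-6, n0 = 10,
                         chrom_length = 1e7, max_generations = 3000)
  run_crash <- run_simulation(cfg_crash, seed = 51)
  expect_identical(run_crash$status, "population_crash")
  expect_lt(tail(run_crash$trajectory$mean_fitness, 1), 1e-3)

  # fitness stays a probability throughout
  expect_true(all(run_crash$trajectory$mean_fitness >= 0 &
                    run_crash$trajectory$mean_fitness <= 1))
})
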