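pop3 <- make_test_population(list(cbind(0, c(100, 200, 300), 0)))
ind3 <- te_individual(pop3, 1)

test_that("silencing magnitudes follow the copy-number-dependent Poisson law", {
  empty <- te_individual(make_test_population(list(NULL, NULL)), 1)
  expect_identical(draw_silencing(empty, 0.02), integer(0))

  # mean a * n: n = 100 copies at a = 0.02 gives mean 2 per copy
  pop100 <- make_test_population(list(cbind(0, 1:100, 0)))
  ind100 <- te_individual(pop100, 1)
  set.seed(8)
  draws <- replicate(1000, mean(draw_silencing(ind100, 0.02)))
  expect_within_sigma(mean(draws), 2, sqrt(2 / (1000 * 100)))

  # single copy: P(M = 0) = exp(-0.02)
  pop1 <- make_test_population(list(cbind(0, 5, 0)))
  ind1 <- te_individual(pop1, 1)
  set.seed(9)
  zeros <- mean(replicate(4000, draw_silencing(ind1, 0.02)) == 0)
  p0 <- exp(-0.02)
  expect_within_sigma(zeros, p0, sqrt(p0 * (1 - p0) / 4000))

  expect_error(draw_silencing(ind3, a_eff = 0), "positive")
})

test_that("effective selection inflates and transposition clamps with M", {
  expect_equal(effective_selection_coefficient(1e-3, 0.2, 0), 1e-3)
  expect_equal(effective_selection_coefficient(1e-3, 0.2, 5), 2e-3)
  expect_equal(effective_selection_coefficient(1e-3, 20, 1), 2.1e-2)

  expect_equal(effective_transposition_rate(0.01, 0.2, 0), 0.01)
  expect_equal(effective_transposition_rate(0.01, 0.2, 5), 0)
  expect_equal(effective_transposition_rate(0.01, 0.2, 6), 0)  # clamped
  # monotonicity over M
  M <- 0:10
  expect_true(all(diff(effective_selection_coefficient(1e-3, 0.2, M)) >= 0))
  expect_true(all(diff(effective_transposition_rate(0.01, 0.2, M)) <= 0))
})

test_that("fitness follows the configured interaction mode", {
  mk_ind <- function(n) te_individual(
    make_test_population(list(if (n > 0) cbind(0, seq_len(n), 0))), 1)

  add <- tiny_cfg(s = 1e-3, fitness_mode = "additive")
  mult <- tiny_cfg(s = 1e-3, fitness_mode = "multiplicative")
  syn <- tiny_cfg(s = 2e-5, fitness_mode = "synergistic")

  # no TEs, no load, in every mode
  for (cfg in list(add, mult, syn))
    expect_equal(individual_fitness(mk_ind(0), cfg), 1)

  expect_equal(individual_fitness(mk_ind(10), add), 1 - 1e-3 * 10)
  expect_equal(individual_fitness(mk_ind(10), mult), (1 - 1e-3)^10)
  expect_equal(individual_fitness(mk_ind(100), syn), 0.8)  # 1 - 2e-5 * 1e4
  # additive load beyond 1 clamps to zero
  expect_equal(individual_fitness(mk_ind(1500), add), 0)

  # silencing side effect: per-copy s_i' summed / multiplied
  add_b <- tiny_cfg(s = 1e-3, b = 0.2, fitness_mode = "additive")
  expect_equal(individual_fitness(mk_ind(2), add_b, M = c(0, 5)),
               1 - (1e-3 + 2e-3))
  mult_b <- tiny_cfg(s = 1e-3, b = 0.2, fitness_mode = "multiplicative")
  expect_equal(individual_fitness(mk_ind(2), mult_b, M = c(0, 5)),
               (1 - 1e-3) * (1 - 2e-3))
  expect_error(individual_fitness(mk_ind(2), add_b), "M")

  syn_b <- tiny_cfg(s = 1e-3, fitness_mode = "synergistic")
  syn_b$b <- 0.2  # bypass constructor to hit the runtime guard
  expect_error(individual_fitness(mk_ind(2), syn_b), "fitness_mode")
})

test_that("b = 0 reduces the silenced model to the plain fitness laws", {
  set.seed(10)
  for (mode in c("additive", "multiplicative")) {
    cfg <- tiny_cfg(s = 2e-3, fitness_mode = mode)
    for (n in c(1, 17, 240)) {
      ind <- te_individual(
        make_test_population(list(cbind(0, seq_len(n), 0))), 1)
      plain <- if (mode == "additive") 1 - cfg$s * n else (1 - cfg$s)^n
      expect_equal(individual_fitness(ind, cfg, M = rpois(n, 3)),
                   max(0, plain))
    }
  }
})

test_that("multiplicative and additive fitness agree to first order", {
  for (s in c(1e-4, 1e-3)) {
    for (n in c(10, 100, 900)) {
      if (s * n >= 0.1) next
      w_add <- 1 - s * n
      w_mult <- (1 - s)^n
      expect_lte(abs(w_mult - w_add), (s * n)^2)
    }
  }
})

test_that("expected silenced additive fitness matches 1 - s n (1 + b a n)", {
  cfg <- tiny_cfg(s = 1e-4, b = 0.2, fitness_mode = "additive")
  a <- 0.02
  set.seed(12)
  for (n in c(10, 100)) {
    ind <- te_individual(make_test_population(list(cbind(0, seq_len(n), 0))), 1)
    n_rep <- 2000
    w <- replicate(n_rep, {
      M <- draw_silencing(ind, a)
      individual_fitness(ind, cfg, M = M)
    })
    expected <- 1 - cfg$s * n * (1 + cfg$b * a * n)
    expect_within_sigma(mean(w), expected, stats::sd(w) / sqrt(n_rep), 3)
  }
})

test_that("fitness is non-increasing in copy number in every mode", {
  for (mode in c("additive", "multiplicative", "synergistic")) {
    cfg <- tiny_cfg(s = 1e-3, fitness_mode = mode)
    w <- vapply(c(0, 1, 5, 20, 100, 500), function(n) {
      ind <- te_individual(
        make_test_population(list(if (n > 0) cbind(0, seq_len(n), 0))), 1)
      individual_fitness(ind, cfg)
    }, numeric(1))
    expect_true(all(diff(w) <= 0))
  }
})

test_that("engine fitness agrees with the R implementation", {
  set.seed(13)
  cases <- expand.grid(mode = c("additive", "multiplicative", "synergistic"),
                       b = c(0, 0.2, 2), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    mode <- cases$mode[i]; b <- cases$b[i]
    if (mode == "synergistic" && b > 0) next
    cfg <- tiny_cfg(s = 2e-3, fitness_mode = mode)
    cfg$b <- b
    for (n in c(0, 3, 50)) {
      ins <- if (n > 0) cbind(0L, seq_len(n), 0L) else
        matrix(integer(0), ncol = 3)
      M <- if (n > 0) rpois(n, 2) else integer(0)
      ind <- te_individual(make_test_population(list(ins)), 1)
      expect_equal(
        tesim:::cpp_individual_fitness(cfg, tesim:::as_ins_matrix(ins),
                                       as.integer(M)),
        individual_fitness(ind, cfg, M = M)
      )
    }
  }
})
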