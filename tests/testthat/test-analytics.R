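# Independent oracle: locate the equilibrium by a dense sign scan of the
# net per-copy growth rate, without any root-finding algebra.
scan_root <- function(u, s, a = 0.02, b = 0, k = 0, mode = "additive",
                      n_max = 2e4) {
  n <- seq(0.5, n_max, by = 0.5)
  f <- te_balance_function(n, u, s, a, b, k, mode)
  i <- which(!is.na(f[-1]) & !is.na(f[-length(f)]) &
               f[-length(f)] > 0 & f[-1] <= 0)
  if (!length(i)) return(NA_real_)
  mean(n[c(i[1], i[1] + 1)])
}

test_that("closed-form equilibria match the sign-scan oracle", {
  # no silencing: n_hat = (u - s) / (u s)
  eq <- analytic_equilibrium(u = 0.01, s = 1e-3)
  expect_equal(eq$n_hat, 900)
  expect_true(eq$stable)
  expect_lt(abs(eq$n_hat - scan_root(0.01, 1e-3)), 0.5)
  expect_equal(analytic_equilibrium(u = 0.1, s = 0.01)$n_hat, 90)

  # silencing on selection: root of u s b a n^2 + (u s + 2 s b a) n = u - s
  eq_b <- analytic_equilibrium(u = 0.01, s = 1e-3, b = 0.2)
  expect_equal(eq_b$n_hat, 300)
  expect_true(eq_b$stable)
  expect_lt(abs(eq_b$n_hat - scan_root(0.01, 1e-3, b = 0.2)), 0.5)

  # silencing on transposition: the expected clamped rate E[u (1 - kM)^+]
  # keeps a Poisson-tail trickle of transposition, so the equilibrium sits
  # above the first-order clamp point 1 / (k a) = 250
  eq_k <- analytic_equilibrium(u = 0.01, s = 1e-3, k = 0.2)
  expect_lt(abs(eq_k$n_hat - scan_root(0.01, 1e-3, k = 0.2)), 0.5)
  expect_gt(eq_k$n_hat, 250)
  expect_lt(eq_k$n_hat, 350)
  expect_true(eq_k$stable)
  # independent check of the expected effective rate by Monte Carlo
  set.seed(70)
  lam <- 0.02 * eq_k$n_hat
  mc <- mean(pmax(0, 1 - 0.2 * rpois(2e5, lam))) * 0.01
  expect_within_sigma(mean_effective_u(0.01, 0.2, lam), mc,
                      0.01 * sd(pmax(0, 1 - 0.2 * rpois(2e5, lam))) / sqrt(2e5))

  # synergistic: u s n^2 + 2 s n = u
  eq_syn <- analytic_equilibrium(u = 0.01, s = 1e-3, mode = "synergistic")
  expect_lt(abs(eq_syn$n_hat - scan_root(0.01, 1e-3, mode = "synergistic")), 0.5)
  expect_true(eq_syn$stable)

  # combined effects (the cubic, solved numerically)
  eq_bk <- analytic_equilibrium(u = 0.01, s = 1e-3, b = 0.2, k = 0.2)
  expect_lt(abs(eq_bk$n_hat - scan_root(0.01, 1e-3, b = 0.2, k = 0.2)), 0.5)
  expect_true(eq_bk$stable)
  # combined containment is at least as tight as either effect alone
  expect_lt(eq_bk$n_hat, eq_b$n_hat)
  expect_lt(eq_bk$n_hat, eq_k$n_hat)
})

test_that("multiplicative fitness without silencing admits no equilibrium", {
  for (s in c(2e-3, 1e-3, 1e-2)) {
    eq <- analytic_equilibrium(u = 0.01, s = s, mode = "multiplicative")
    expect_true(is.na(eq$n_hat))
    expect_identical(eq$reason,
                     if (-log(1 - s) < 0.01) "unbounded_growth" else "te_loss")
  }
})

test_that("equilibrium absence is explained by the net growth sign", {
  expect_identical(analytic_equilibrium(u = 0.01, s = 0.05)$reason, "te_loss")
  expect_identical(analytic_equilibrium(u = 0, s = 1e-3)$reason, "te_loss")
  expect_identical(analytic_equilibrium(u = 0.01, s = 0)$reason,
                   "unbounded_growth")
})

test_that("equilibrium copy number moves the right way with u, s and b", {
  u_grid <- c(0.005, 0.01, 0.05, 0.1)
  n_u <- vapply(u_grid, function(u)
    analytic_equilibrium(u = u, s = 1e-3)$n_hat, numeric(1))
  expect_true(all(diff(n_u) > 0))     # increasing in u

  s_grid <- c(2e-4, 5e-4, 1e-3, 2e-3)
  n_s <- vapply(s_grid, function(s)
    analytic_equilibrium(u = 0.01, s = s)$n_hat, numeric(1))
  expect_true(all(diff(n_s) < 0))     # decreasing in s

  # silencing costs strictly reduce the equilibrium copy number
  for (s in c(1e-4, 1e-3)) {
    plain <- analytic_equilibrium(u = 0.01, s = s)$n_hat
    cost <- analytic_equilibrium(u = 0.01, s = s, b = 0.2)$n_hat
    expect_lt(cost, plain)
  }
})

test_that("effective-rate ratios evaluate the silencing means at n_hat", {
  r1 <- effective_rate_ratios(300, u = 0.01, s = 1e-3, b = 0.2)
  expect_equal(r1$effective_s_over_u, 1e-3 * (1 + 0.2 * 0.02 * 300) / 0.01)
  expect_equal(r1$effective_s_over_u, 0.22)

  # at equilibrium u_eff * wbar = s, so s / u_eff equals the expected
  # fitness 1 - s n_hat: an identity that checks solver and ratio together
  eq_k <- analytic_equilibrium(u = 0.01, s = 1e-3, k = 0.2)
  r2 <- effective_rate_ratios(eq_k, u = 0.01, s = 1e-3, k = 0.2)
  expect_equal(r2$s_over_effective_u, 1 - 1e-3 * eq_k$n_hat,
               tolerance = 1e-6)

  r0 <- effective_rate_ratios(500, u = 0.01, s = 1e-3)
  expect_equal(r0$effective_s_over_u, 0.1)
  expect_equal(r0$s_over_effective_u, 0.1)

  # without transposition there is no effective rate to take a ratio of
  r3 <- effective_rate_ratios(300, u = 0, s = 1e-3, k = 0.2)
  expect_true(is.na(r3$s_over_effective_u))
})

test_that("relative variance is the among-replicate variance over the mean", {
  expect_equal(relative_variance(c(100, 110, 90)), 1)
  expect_equal(relative_variance(c(50, 50, 50, 50)), 0)
  expect_equal(relative_variance(c(10, 1000)), 490050 / 505)
  expect_error(relative_variance(100), "two replicates")
  expect_error(relative_variance(c(0, 0)), "not positive")
})

fake_run <- function(cn, status = "completed", w = NULL) {
  g <- seq_along(cn) - 1
  if (is.null(w)) w <- rep(0.9, length(cn))
  structure(list(trajectory = data.frame(
    generation = g, mean_copy_number = cn, mean_fitness = w,
    modifier_frequency = 0), status = status,
    generations_run = max(g), final_population = NULL), class = "te_run")
}

test_that("outcome classification follows the replicate decision rule", {
  set.seed(71)
  # flat trajectories around 900 with small noise: stable at N s = 10
  flat <- replicate(5, fake_run(900 + rnorm(1500, 0, 3)), simplify = FALSE)
  out <- classify_outcome(flat, N = 1e4, s = 1e-3, window = 1000)
  expect_identical(out$label, "stable_equilibrium")
  expect_lt(out$relative_variance, 1 / (1e4 * 1e-3))

  # majority loss / crash
  lost <- c(replicate(3, fake_run(c(10, 5, 0), "te_loss"), simplify = FALSE),
            replicate(2, fake_run(900 + rnorm(1500)), simplify = FALSE))
  expect_identical(classify_outcome(lost, 1e4, 1e-3, 1000)$label, "te_loss")
  crashed <- replicate(3, fake_run(c(10, 100, 1000), "population_crash",
                                   w = c(0.9, 0.5, 5e-4)), simplify = FALSE)
  expect_identical(classify_outcome(crashed, 1e4, 1e-3, 1000)$label,
                   "population_crash")

  # a clear linear trend is not a plateau
  set.seed(72)
  trend <- replicate(3, fake_run(seq(100, 400, length.out = 1500) +
                                   rnorm(1500, 0, 2)), simplify = FALSE)
  expect_identical(classify_outcome(trend, 1e4, 1e-3, 1000)$label,
                   "unsettled")

  # runs shorter than the plateau window cannot be called stable
  short <- replicate(3, fake_run(rep(900, 200)), simplify = FALSE)
  expect_identical(classify_outcome(short, 1e4, 1e-3, 1000)$label,
                   "unsettled")

  # replicate scatter above 1 / (N s) vetoes stability even when flat
  set.seed(73)
  scattered <- lapply(c(500, 900, 1400), function(m)
    fake_run(m + rnorm(1500, 0, 2)))
  out_sc <- classify_outcome(scattered, 1e4, 1e-3, 1000)
  expect_identical(out_sc$label, "unsettled")
  expect_gt(out_sc$relative_variance, 0.1)
})

test_that("simulated equilibria agree with the analytic solution", {
  # scaled oracle-equivalence check: strong rates keep the run short
  cfg <- te_config(N = 500, u = 0.1, s = 0.01, r = 1e-6, n0 = 10,
                   chrom_length = 5e7, max_generations = 700, seed = 74)
  runs <- run_replicates(cfg, replicates = 2)
  n_hat <- analytic_equilibrium(u = 0.1, s = 0.01)$n_hat
  finals <- vapply(runs, function(r) {
    tr <- r$trajectory
    mean(tr$mean_copy_number[tr$generation > 400])
  }, numeric(1))
  expect_lt(abs(mean(finals) - n_hat) / n_hat, 0.15)
})
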