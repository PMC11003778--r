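## Transposition-selection balance: analytical equilibria, effective-rate
## ratios, and the replicate-level outcome classifier.
##
## In an infinite population the equilibrium diploid copy number n_hat
## solves u_eff(n) = -d ln wbar(n) / dn, where wbar(n) is the expected
## fitness at copy number n (silencing magnitudes averaged over their
## Poisson distribution) and u_eff(n) the expected per-copy transposition
## rate E[u (1 - k M)^+] at M ~ Poisson(a n).  An equilibrium is stable
## when the net per-copy growth rate crosses zero from above.

#' Expected effective transposition rate under silencing
#'
#' The mean of the per-copy clamped rate `u (1 - k M)^+` over
#' `M ~ Poisson(lambda)`: `u * sum_{m : k m < 1} (1 - k m) P(M = m)`.
#' Unlike the first-order form `u (1 - k a n)`, this expectation stays
#' positive for every copy number (the Poisson mass near zero always
#' leaves some copies weakly silenced), which is what the simulation
#' realizes.
#'
#' @param u Baseline transposition rate.
#' @param k Silencing transposition multiplier.
#' @param lambda Poisson mean of the silencing magnitude (vectorized;
#'   `a * n` at copy number `n`).
#' @return Expected effective transposition rate.
#' @export
mean_effective_u <- function(u, k, lambda) {
  if (k <= 0) return(rep_len(u, length(lambda)))
  acc <- numeric(length(lambda))
  m <- 0
  while (k * m < 1) {
    acc <- acc + (1 - k * m) * stats::dpois(m, lambda)
    m <- m + 1
  }
  u * acc
}

#' Expected log-fitness gradient and net growth rate
#'
#' `te_balance_function(n, ...)` returns the expected per-copy log growth
#' rate `f(n) = u_eff(n) + d ln wbar / dn`, with
#' `u_eff = ` [mean_effective_u()] at `lambda = a n`; its positive roots are
#' candidate equilibria.  Exposed for inspection and independent
#' verification.
#'
#' @param n Copy number (vectorized, treated as continuous).
#' @param u,s,a,b,k Model parameters (see [te_config()]).
#' @param mode `"additive"`, `"multiplicative"` or `"synergistic"`.
#' @return `f(n)`; `NA` where expected fitness is non-positive.
#' @export
te_balance_function <- function(n, u, s, a = 0.02, b = 0, k = 0,
                                mode = "additive") {
  u_eff <- mean_effective_u(u, k, a * n)
  dlnw <- switch(mode,
    additive = {
      w <- 1 - s * n - s * b * a * n^2
      ifelse(w > 0, -(s + 2 * s * b * a * n) / w, NA_real_)
    },
    multiplicative = {
      s_t <- s * (1 + b * a * n)
      ifelse(s_t < 1, log(1 - s_t) - n * s * b * a / (1 - s_t), NA_real_)
    },
    synergistic = {
      w <- 1 - s * n^2
      ifelse(w > 0, -2 * s * n / w, NA_real_)
    },
    stop("unknown mode: ", mode)
  )
  u_eff + dlnw
}

#' Analytical equilibrium TE copy number
#'
#' Solves the transposition-selection balance for the configured fitness and
#' silencing variant.  Where the algebra permits (no silencing; silencing on
#' selection only; synergistic) the root is closed-form; any case with
#' silencing of transposition (`k > 0`, whose expected effective rate is the
#' Poisson tail sum of [mean_effective_u()]) or with combined effects is
#' solved by bracketed numerical root-finding.  Roots at which expected
#' fitness is non-positive are rejected.
#'
#' @inheritParams te_balance_function
#' @return A list of class `"te_equilibrium"`: `n_hat` (equilibrium diploid
#'   copy number, `NA` when absent), `stable` (logical, `NA` when no
#'   equilibrium), `mode`, `w_bar` (expected fitness at `n_hat`), and
#'   `reason` (`"ok"`, or why no equilibrium exists: `"te_loss"` when net
#'   growth is negative at small copy number, `"unbounded_growth"`
#'   otherwise).
#' @export
#' @examples
#' analytic_equilibrium(u = 0.01, s = 1e-3)$n_hat                    # 900
#' analytic_equilibrium(u = 0.01, s = 1e-3, b = 0.2)$n_hat           # 300
#' analytic_equilibrium(u = 0.01, s = 2e-3, mode = "multiplicative") # none
analytic_equilibrium <- function(u, s, a = 0.02, b = 0, k = 0,
                                 mode = c("additive", "multiplicative",
                                          "synergistic")) {
  mode <- match.arg(mode)
  stopifnot(u >= 0, s >= 0, b >= 0, k >= 0)
  if ((b > 0 || k > 0) && a <= 0) stop("a must be > 0 when b > 0 or k > 0")
  if (mode == "synergistic" && (b > 0 || k > 0))
    stop("synergistic fitness is defined only with b = 0 and k = 0")

  none <- function(reason) {
    structure(list(n_hat = NA_real_, stable = NA, mode = mode,
                   w_bar = NA_real_, reason = reason),
              class = "te_equilibrium")
  }
  if (u == 0) return(none("te_loss"))
  if (s == 0) return(none("unbounded_growth"))

  root <- solve_balance_root(u, s, a, b, k, mode)
  if (is.na(root)) {
    f0 <- te_balance_function(1e-9, u, s, a, b, k, mode)
    return(none(if (!is.na(f0) && f0 > 0) "unbounded_growth" else "te_loss"))
  }
  w_bar <- expected_fitness(root, s, a, b, mode)
  h <- max(root * 1e-5, 1e-7)
  f_lo <- te_balance_function(root - h, u, s, a, b, k, mode)
  f_hi <- te_balance_function(root + h, u, s, a, b, k, mode)
  stable <- isTRUE(f_hi < f_lo)  # net growth crosses zero from above
  structure(list(n_hat = root, stable = stable, mode = mode,
                 w_bar = w_bar, reason = "ok"),
            class = "te_equilibrium")
}

expected_fitness <- function(n, s, a, b, mode) {
  switch(mode,
    additive = 1 - s * n - s * b * a * n^2,
    multiplicative = (1 - s * (1 + b * a * n))^n,
    synergistic = 1 - s * n^2
  )
}

# Smallest positive root of the balance function within the physical domain
# (expected fitness > 0).  Closed forms where the algebra permits; any case
# with silencing of transposition (k > 0, whose expected rate is a Poisson
# tail sum) or combined effects is bracketed numerically.
solve_balance_root <- function(u, s, a, b, k, mode) {
  if (mode == "additive" && b == 0 && k == 0) {
    if (u <= s) return(NA_real_)
    return((u - s) / (u * s))
  }
  if (mode == "synergistic") {
    # u (1 - s n^2) = 2 s n  ->  u s n^2 + 2 s n - u = 0
    n <- (-s + sqrt(s^2 + u^2 * s)) / (u * s)
    return(if (n > 0) n else NA_real_)
  }
  if (mode == "additive" && b > 0 && k == 0) {
    # u s b a n^2 + (u s + 2 s b a) n - (u - s) = 0
    A <- u * s * b * a; B <- u * s + 2 * s * b * a; C <- u - s
    if (C <= 0) return(NA_real_)
    n <- (-B + sqrt(B^2 + 4 * A * C)) / (2 * A)
    return(if (n > 0) n else NA_real_)
  }

  # General case: bracketed root-finding on the balance function.
  n_max <- 1e6
  if (mode == "additive") {
    w_zero <- if (b > 0)
      (-s + sqrt(s^2 + 4 * s * b * a)) / (2 * s * b * a) else 1 / s
    n_max <- min(n_max, w_zero)
  } else if (mode == "multiplicative" && b > 0) {
    n_max <- min(n_max, (1 - s) / (s * b * a))
  }
  lo <- 1e-6
  f_lo <- te_balance_function(lo, u, s, a, b, k, mode)
  if (is.na(f_lo) || f_lo <= 0) return(NA_real_)
  # scan for a sign change on a log-spaced grid, then refine
  grid <- exp(seq(log(lo), log(n_max * (1 - 1e-9)), length.out = 400))
  fv <- te_balance_function(grid, u, s, a, b, k, mode)
  idx <- which(!is.na(fv[-1]) & !is.na(fv[-length(fv)]) &
                 fv[-length(fv)] > 0 & fv[-1] <= 0)
  if (!length(idx)) return(NA_real_)
  i <- idx[1L]
  stats::uniroot(function(n) te_balance_function(n, u, s, a, b, k, mode),
                 lower = grid[i], upper = grid[i + 1L], tol = 1e-9)$root
}

#' Effective-rate ratios at an equilibrium copy number
#'
#' At equilibrium copy number `n_hat` the silencing magnitudes are
#' `M ~ Poisson(a * n_hat)`, so the mean effective selection coefficient
#' over copies is `s (1 + b a n_hat)` and the mean effective transposition
#' rate is [mean_effective_u()] at `lambda = a * n_hat` (the average of the
#' clamped per-copy rate).  Returns the two headline ratios.
#'
#' @param n_hat Equilibrium diploid copy number (a number or a
#'   `te_equilibrium`); a simulated equilibrium mean works the same way.
#' @inheritParams te_balance_function
#' @return List with `effective_s_over_u` = `s (1 + b a n_hat) / u` and
#'   `s_over_effective_u` = `s / u_eff(n_hat)` (`NA` when the effective
#'   transposition rate is 0, i.e. when `u = 0`).
#' @export
#' @examples
#' effective_rate_ratios(300, u = 0.01, s = 1e-3, b = 0.2)$effective_s_over_u
effective_rate_ratios <- function(n_hat, u, s, a = 0.02, b = 0, k = 0) {
  if (inherits(n_hat, "te_equilibrium")) n_hat <- n_hat$n_hat
  stopifnot(is.numeric(n_hat), length(n_hat) == 1L)
  if (is.na(n_hat)) stop("no equilibrium copy number available")
  s_eff <- s * (1 + b * a * n_hat)
  u_eff <- mean_effective_u(u, k, a * n_hat)
  list(effective_s_over_u = if (u > 0) s_eff / u else NA_real_,
       s_over_effective_u = if (u_eff > 0) s / u_eff else NA_real_)
}

#' Relative variance of replicate copy numbers
#'
#' Sample variance across replicate means divided by their grand mean; the
#' among-replicate reproducibility statistic compared against `1 / (N s)`
#' when declaring a stable equilibrium.
#'
#' @param x Numeric vector of per-replicate copy numbers (>= 2 values).
#' @return `var(x) / mean(x)`.
#' @export
#' @examples
#' relative_variance(c(100, 110, 90))  # 1
relative_variance <- function(x) {
  if (length(x) < 2L) stop("need at least two replicates")
  m <- mean(x)
  if (m <= 0) stop("undefined relative variance: mean copy number is not positive")
  stats::var(x) / m
}

is_plateau <- function(gen, y, alpha, flat_tol) {
  if (length(y) < 3L || stats::var(y) == 0) return(TRUE)
  fit <- stats::lm(y ~ gen)
  cf <- summary(fit)$coefficients
  if (nrow(cf) < 2L || !is.finite(cf[2L, 4L])) return(TRUE)
  if (cf[2L, 4L] >= alpha) return(TRUE)
  # practical equivalence: a fitted net change is only a real departure
  # from stationarity when it exceeds both a fixed fraction of the level
  # and the series' own fluctuation scale
  drift <- abs(cf[2L, 1L]) * (max(gen) - min(gen))
  drift <= max(flat_tol * mean(y), 2 * stats::sd(stats::residuals(fit)))
}

#' Classify the outcome of replicate simulations
#'
#' Applies the replicate-level decision rule: `te_loss` when the majority of
#' replicates lost all copies; `population_crash` when the majority crashed
#' (mean fitness below 0.1%) or went extinct; `stable_equilibrium` when the
#' majority of completed replicates plateau over the final `window`
#' generations *and* the relative variance of final copy numbers across
#' replicates is below `1 / (N s)`; otherwise `unsettled`.  Ties are
#' `unsettled`.
#'
#' A replicate plateaus when its OLS slope of mean copy number over the
#' window is not significantly different from zero (two-sided p >= `alpha`),
#' *or* when the fitted net change over the window is below `flat_tol` of
#' the window mean.  The second clause keeps the test honest on long
#' autocorrelated series, where vanishing standard errors declare
#' biologically negligible drifts "significant".
#'
#' @param runs List of `te_run` objects (see [run_simulation()]), one per
#'   replicate of the same configuration.
#' @param N Census population size of the runs.
#' @param s Selection coefficient of the runs.
#' @param window Plateau window in generations (default 5000; scale down
#'   with shorter runs).
#' @param alpha Significance level for the trend test.
#' @param flat_tol Practical-equivalence bound: maximum fitted net change
#'   over the window, as a fraction of the window mean, still counted as
#'   flat (default 0.05).
#' @return A list of class `"te_outcome"`: `label`, `relative_variance`,
#'   `threshold` (`1/(N s)`), `mean_copy_number` (grand mean over final
#'   generations of completed replicates), `replicate_status`, and
#'   `plateau` (logical per replicate, `NA` when not evaluable).
#' @export
classify_outcome <- function(runs, N, s, window = 5000, alpha = 0.01,
                             flat_tol = 0.05) {
  stopifnot(length(runs) >= 1L)
  status <- vapply(runs, function(r) r$status, character(1))
  n_rep <- length(runs)
  majority <- function(m) m > n_rep / 2

  if (majority(sum(status == "te_loss")))
    return(te_outcome("te_loss", NA, N, s, NA, status, rep(NA, n_rep)))
  if (majority(sum(status %in% c("population_crash", "extinct"))))
    return(te_outcome("population_crash", NA, N, s, NA, status, rep(NA, n_rep)))

  plateau <- rep(NA, n_rep)
  finals <- rep(NA_real_, n_rep)
  for (i in seq_len(n_rep)) {
    if (status[i] != "completed") next
    tr <- runs[[i]]$trajectory
    gmax <- max(tr$generation)
    keep <- tr$generation > gmax - window
    if (gmax < window || sum(keep) < 3L) next
    plateau[i] <- is_plateau(tr$generation[keep], tr$mean_copy_number[keep],
                             alpha, flat_tol)
    finals[i] <- tr$mean_copy_number[nrow(tr)]
  }
  ok <- !is.na(finals)
  rv <- if (sum(ok) >= 2L && mean(finals[ok]) > 0)
    relative_variance(finals[ok]) else NA_real_
  threshold <- 1 / (N * s)
  label <- if (majority(sum(plateau, na.rm = TRUE)) &&
               !is.na(rv) && rv < threshold) "stable_equilibrium" else "unsettled"
  te_outcome(label, rv, N, s, if (any(ok)) mean(finals[ok]) else NA_real_,
             status, plateau)
}

te_outcome <- function(label, rv, N, s, mean_cn, status, plateau) {
  structure(list(label = label, relative_variance = rv,
                 threshold = 1 / (N * s), mean_copy_number = mean_cn,
                 replicate_status = status, plateau = plateau),
            class = "te_outcome")
}

#' @export
print.te_outcome <- function(x, ...) {
  cat(sprintf("<te_outcome> %s\n", x$label))
  if (!is.na(x$relative_variance))
    cat(sprintf("  relative variance %.4g (threshold 1/Ns = %.4g)\n",
                x$relative_variance, x$threshold))
  if (!is.na(x$mean_copy_number))
    cat(sprintf("  mean copy number %.1f\n", x$mean_copy_number))
  cat("  replicates:", paste(x$replicate_status, collapse = ", "), "\n")
  invisible(x)
}

#' Initial copy number for equilibrium-targeted runs
#'
#' For grid experiments aimed at equilibrium behaviour, a sensible starting
#' copy number is well below the predicted equilibrium (so the growth phase
#' is visible) but not so small that the approach dominates the runtime,
#' and never so large that the founding cohort is already inviable.
#' Returns `n_hat / 10` clamped to `[2, 100]` when a stable equilibrium is
#' predicted; otherwise the largest count up to 10 whose expected initial
#' load stays below one half.
#'
#' @param cfg A [te_config()].
#' @return Integer initial copy number.
#' @export
suggest_n0 <- function(cfg) {
  eq <- analytic_equilibrium(cfg$u, cfg$s, cfg$a, cfg$b, cfg$k,
                             mode = cfg$fitness_mode)
  if (!is.na(eq$n_hat) && isTRUE(eq$stable))
    return(as.integer(max(2, min(100, round(eq$n_hat / 10)))))
  # no equilibrium: keep the founding load below 1/2 in expectation
  viable <- function(n) {
    w <- expected_fitness(n, cfg$s, cfg$a, cfg$b, cfg$fitness_mode)
    !is.na(w) && w >= 0.5
  }
  n0 <- 10L
  while (n0 > 1L && !viable(n0)) n0 <- n0 - 1L
  n0
}

# Horizon (generations) for a configuration to settle: numerical
# integration of the mean-field dynamics dn/dt = n f(n) from n0 to 95% of
# the equilibrium (or down to 105% when starting above it), with slack,
# plus the plateau window.  Loss and crash runs terminate on their own, so
# configurations without a stable equilibrium get the configured maximum.
suggest_horizon <- function(cfg, window = 1500, slack = 1.3) {
  eq <- analytic_equilibrium(cfg$u, cfg$s, cfg$a, cfg$b, cfg$k,
                             mode = cfg$fitness_mode)
  if (is.na(eq$n_hat) || !isTRUE(eq$stable)) return(cfg$max_generations)
  n0 <- max(cfg$n0, 1)
  target <- if (n0 < eq$n_hat) 0.95 * eq$n_hat else 1.05 * eq$n_hat
  if ((n0 < target) == (n0 > eq$n_hat)) return(as.integer(
    min(cfg$max_generations, window + 400)))
  grid <- exp(seq(log(n0), log(target), length.out = 400))
  mid <- sqrt(grid[-1] * grid[-length(grid)])
  f <- te_balance_function(mid, cfg$u, cfg$s, cfg$a, cfg$b, cfg$k,
                           cfg$fitness_mode)
  dt <- abs(diff(grid)) / (mid * abs(f))
  dt <- dt[is.finite(dt)]
  settle <- slack * sum(dt)
  as.integer(min(cfg$max_generations, ceiling(settle) + window + 200))
}
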