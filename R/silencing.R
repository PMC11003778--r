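## Epigenetic silencing: per-copy magnitudes, effective rates and fitness.
##
## Silencing is re-established every generation: each of an individual's n
## copies draws an integer magnitude M ~ Poisson(a' * n), where a' is the
## individual's effective silencing scale (a, rescaled by any modifier
## genotype).  One draw serves all three consumers -- selection inflation,
## transposition suppression and ectopic-recombination eligibility.

#' Draw per-copy silencing magnitudes
#'
#' @param individual A `te_individual` (or anything with a diploid copy
#'   number via [copy_number()]).
#' @param a_eff Effective silencing scale `a'` (> 0); see
#'   [effective_silencing_parameter()] for modifier carriers.
#' @return Integer vector of length `n` (the copy number): magnitudes
#'   `M_i ~ Poisson(a_eff * n)`, independent across copies.
#' @export
#' @examples
#' pop <- make_test_population(list(cbind(0, c(100, 200, 300), 0)))
#' set.seed(1)
#' draw_silencing(te_individual(pop, 1), a_eff = 0.02)
draw_silencing <- function(individual, a_eff) {
  if (!is.numeric(a_eff) || length(a_eff) != 1L || a_eff <= 0)
    stop("`a_eff` must be a single positive number")
  n <- copy_number(individual)
  if (n == 0L) return(integer(0))
  stats::rpois(n, a_eff * n)
}

#' Effective selection coefficient of a silenced TE copy
#'
#' The spreading of repressive marks from a silenced copy inflates selection
#' against it: `s' = s * (1 + b * M)`.
#'
#' @param s Baseline selection coefficient per copy.
#' @param b Silencing selection multiplier.
#' @param M Silencing magnitude(s); vectorized.
#' @return `s * (1 + b * M)`.
#' @export
effective_selection_coefficient <- function(s, b, M) {
  stopifnot(s >= 0, b >= 0, all(M >= 0))
  s * (1 + b * M)
}

#' Effective transposition rate of a silenced TE copy
#'
#' Silencing suppresses replication: `u' = u * (1 - k * M)`, floored at zero.
#'
#' @param u Baseline transposition rate per copy.
#' @param k Silencing transposition multiplier.
#' @param M Silencing magnitude(s); vectorized.
#' @return `max(0, u * (1 - k * M))`.
#' @export
effective_transposition_rate <- function(u, k, M) {
  stopifnot(u >= 0, k >= 0, all(M >= 0))
  pmax(0, u * (1 - k * M))
}

#' Individual fitness under a TE load
#'
#' Computes the sampling weight `W` for the configured interaction mode:
#' additive `W = 1 - s n`, multiplicative `W = (1 - s)^n`, synergistic
#' `W = 1 - s n^2`.  When the silencing side effect is on (`b > 0`) the
#' additive and multiplicative forms use per-copy effective coefficients
#' `s_i' = s (1 + b M_i)` (sum and product respectively).  The result is
#' clamped to `[0, 1]`; each multiplicative factor is floored at 0.
#'
#' @param individual A `te_individual` (or anything accepted by
#'   [copy_number()]).
#' @param cfg A [te_config()] supplying `s`, `b` and `fitness_mode`.
#' @param M Integer vector of per-copy silencing magnitudes; required when
#'   `cfg$b > 0` (length must equal the copy number), ignored otherwise.
#' @return Fitness in `[0, 1]`; exactly 1 when the copy number is 0.
#' @export
#' @examples
#' cfg <- te_config(N = 10, s = 2e-5, fitness_mode = "synergistic",
#'                  max_generations = 1)
#' pop <- make_test_population(list(cbind(0, 1:100, 0)))
#' individual_fitness(te_individual(pop, 1), cfg)  # 1 - 2e-5 * 100^2 = 0.8
individual_fitness <- function(individual, cfg, M = NULL) {
  cfg <- validate_te_config(cfg)
  n <- copy_number(individual)
  if (n == 0L) return(1)
  mode <- cfg$fitness_mode
  if (mode == "synergistic" && cfg$b > 0)
    stop("synergistic fitness with silencing side effects (b > 0) is not defined")
  if (cfg$b > 0) {
    if (is.null(M)) stop("per-copy silencing magnitudes `M` are required when b > 0")
    if (length(M) != n) stop("length(M) must equal the copy number")
    s_eff <- effective_selection_coefficient(cfg$s, cfg$b, M)
    W <- switch(mode,
      additive = 1 - sum(s_eff),
      multiplicative = prod(pmax(0, 1 - s_eff))
    )
  } else {
    W <- switch(mode,
      additive = 1 - cfg$s * n,
      multiplicative = (1 - cfg$s)^n,
      synergistic = 1 - cfg$s * n^2
    )
  }
  min(1, max(0, W))
}
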