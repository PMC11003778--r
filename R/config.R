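#' Simulation configuration
#'
#' Build and validate the single source of truth for one simulation run.
#' Every model parameter and run-control setting lives here; all other
#' functions take a `te_config` rather than loose arguments.
#'
#' @param N Census population size (diploid individuals). Constant across
#'   generations (Wright-Fisher).
#' @param u Transposition probability per TE copy per generation, in `[0, 1]`.
#' @param s Selection coefficient per TE copy, in `[0, 1]`.
#' @param r Crossover probability per bp per meiosis (`r*chrom_length` is
#'   the expected crossover count per chromosome).
#' @param fitness_mode One of `"additive"`, `"multiplicative"`,
#'   `"synergistic"`: how per-copy fitness effects combine.
#' @param a Silencing-strength scale: each copy's silencing magnitude is
#'   drawn `M ~ Poisson(a * n)` with `n` the individual's diploid copy
#'   number.
#' @param b Silencing selection multiplier; `s_i' = s * (1 + b * M_i)`.
#'   `0` switches the spreading side effect off.
#' @param k Silencing transposition multiplier;
#'   `u_i' = max(0, u * (1 - k * M_i))`. `0` switches suppression off.
#' @param n0 Initial TE copies per individual.
#' @param chrom_length Chromosome length in bp.
#' @param n_chroms Number of chromosomes (per haploid genome).
#' @param max_generations Maximum number of generations to simulate.
#' @param burn_in_generations Generations simulated before a modifier allele
#'   is introduced in invasion experiments.
#' @param invasion_generations Generations simulated after the modifier is
#'   introduced.
#' @param modifier_direction `"none"`, `"enhance"` or `"weaken"`: whether and
#'   how a modifier allele rescales `a` in carriers (`a' = a (1 +- 0.5 H)`
#'   with `H` = 0.5 in heterozygotes and 1 in homozygotes).
#' @param modifier_init_freq Population allele frequency at which the
#'   modifier is introduced.
#' @param modifier_chrom,modifier_pos Location of the modifier locus
#'   (defaults: middle of chromosome 1, i.e. chromosome index 0).
#' @param r_e Ectopic recombination probability per eligible heterozygous TE
#'   pair per generation; `0` switches the ectopic model off.
#' @param ectopic_suppression If `TRUE`, a copy with silencing magnitude
#'   `M > T` is excluded from ectopic recombination.
#' @param T Per-copy silencing threshold above which ectopic recombination is
#'   fully suppressed for that copy.
#' @param seed Integer seed for the run's random stream.
#' @param replicates Replicate count used by sweep/experiment drivers.
#' @param record_stride Record a trajectory row every `record_stride`
#'   generations (the final generation is always recorded).
#'
#' @return A validated list of class `"te_config"`.
#' @seealso [read_te_config()] to load a config from a YAML file,
#'   [te_profile()] for pre-set scale profiles.
#' @export
#' @examples
#' cfg <- te_config(N = 100, u = 0.01, s = 1e-3, max_generations = 50)
#' cfg$n0
te_config <- function(N = 10000L,
                      u = 0.01,
                      s = 1e-3,
                      r = 1e-6,
                      fitness_mode = c("additive", "multiplicative", "synergistic"),
                      a = 0.02,
                      b = 0,
                      k = 0,
                      n0 = 10L,
                      chrom_length = 5e7,
                      n_chroms = 2L,
                      max_generations = 10000L,
                      burn_in_generations = 5000L,
                      invasion_generations = 5000L,
                      modifier_direction = c("none", "enhance", "weaken"),
                      modifier_init_freq = 0.10,
                      modifier_chrom = 0L,
                      modifier_pos = NULL,
                      r_e = 0,
                      ectopic_suppression = FALSE,
                      T = 5,
                      seed = 1L,
                      replicates = 1L,
                      record_stride = 1L) {
  fitness_mode <- match.arg(fitness_mode)
  modifier_direction <- match.arg(modifier_direction)
  if (is.null(modifier_pos)) modifier_pos <- floor(chrom_length / 2)
  cfg <- list(
    N = as.integer(N), u = u, s = s, r = r,
    fitness_mode = fitness_mode, a = a, b = b, k = k,
    n0 = as.integer(n0),
    chrom_length = as.numeric(chrom_length), n_chroms = as.integer(n_chroms),
    max_generations = as.integer(max_generations),
    burn_in_generations = as.integer(burn_in_generations),
    invasion_generations = as.integer(invasion_generations),
    modifier_direction = modifier_direction,
    modifier_init_freq = modifier_init_freq,
    modifier_chrom = as.integer(modifier_chrom),
    modifier_pos = as.numeric(modifier_pos),
    r_e = r_e, ectopic_suppression = isTRUE(ectopic_suppression), T = T,
    seed = as.integer(seed), replicates = as.integer(replicates),
    record_stride = as.integer(record_stride)
  )
  class(cfg) <- "te_config"
  validate_te_config(cfg)
}

stop_config <- function(field, msg) {
  stop(structure(
    class = c("tesim_config_error", "error", "condition"),
    list(message = sprintf("invalid configuration field `%s`: %s", field, msg),
         call = NULL)
  ))
}

#' Validate a simulation configuration
#'
#' Checks every invariant of the model parameters and errors naming the
#' offending field.
#'
#' @param cfg A `te_config` (or a bare list with the same fields).
#' @return The validated config, invisibly classed as `"te_config"`.
#' @export
validate_te_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(cfg$N) || cfg$N < 2) stop_config("N", "need at least 2 individuals")
  if (!num1(cfg$chrom_length) || cfg$chrom_length <= 0)
    stop_config("chrom_length", "must be > 0")
  if (!num1(cfg$n_chroms) || cfg$n_chroms < 1)
    stop_config("n_chroms", "must be >= 1")
  if (!num1(cfg$u) || cfg$u < 0 || cfg$u > 1)
    stop_config("u", "transposition rate must lie in [0, 1]")
  if (!num1(cfg$s) || cfg$s < 0 || cfg$s > 1)
    stop_config("s", "selection coefficient must lie in [0, 1]")
  if (!num1(cfg$r) || cfg$r < 0) stop_config("r", "crossover rate must be >= 0")
  if (!num1(cfg$a)) stop_config("a", "must be a number")
  if (!num1(cfg$b) || cfg$b < 0) stop_config("b", "must be >= 0")
  if (!num1(cfg$k) || cfg$k < 0) stop_config("k", "must be >= 0")
  if ((cfg$b > 0 || cfg$k > 0) && cfg$a <= 0)
    stop_config("a", "must be > 0 when b > 0 or k > 0")
  if (identical(cfg$fitness_mode, "synergistic") && (cfg$b > 0 || cfg$k > 0))
    stop_config("fitness_mode",
                "synergistic fitness is defined only without silencing effects (b = 0 and k = 0)")
  if (!num1(cfg$n0) || cfg$n0 < 0) stop_config("n0", "must be >= 0")
  if (cfg$n0 > cfg$n_chroms * cfg$chrom_length)
    stop_config("n0", "more initial copies than available (chromosome, position) sites")
  if (!num1(cfg$max_generations) || cfg$max_generations < 1)
    stop_config("max_generations", "must be >= 1")
  if (!num1(cfg$burn_in_generations) || cfg$burn_in_generations < 1)
    stop_config("burn_in_generations", "must be >= 1")
  if (!num1(cfg$invasion_generations) || cfg$invasion_generations < 1)
    stop_config("invasion_generations", "must be >= 1")
  if (!num1(cfg$modifier_init_freq) ||
      cfg$modifier_init_freq < 0 || cfg$modifier_init_freq > 1)
    stop_config("modifier_init_freq", "must lie in [0, 1]")
  if (cfg$modifier_chrom < 0 || cfg$modifier_chrom >= cfg$n_chroms)
    stop_config("modifier_chrom", "chromosome index out of range")
  if (cfg$modifier_pos < 0 || cfg$modifier_pos >= cfg$chrom_length)
    stop_config("modifier_pos", "position outside the chromosome")
  if (!num1(cfg$r_e) || cfg$r_e < 0 || cfg$r_e > 1)
    stop_config("r_e", "ectopic rate must lie in [0, 1]")
  if (!num1(cfg$T) || cfg$T < 0) stop_config("T", "threshold must be >= 0")
  if (!num1(cfg$seed)) stop_config("seed", "must be a single integer")
  if (!num1(cfg$replicates) || cfg$replicates < 1)
    stop_config("replicates", "must be >= 1")
  if (!num1(cfg$record_stride) || cfg$record_stride < 1)
    stop_config("record_stride", "must be >= 1")
  class(cfg) <- "te_config"
  invisible(cfg)
}

#' Read a simulation configuration from a YAML file
#'
#' Keys are exactly the field names of [te_config()]; unknown keys are an
#' error so that typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @param ... Overrides applied after reading (same names as [te_config()]).
#' @return A validated `te_config`.
#' @export
read_te_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("config file must contain a YAML mapping")
  vals <- utils::modifyList(vals, list(...))
  known <- names(formals(te_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(te_config, vals)
}

#' Write a simulation configuration to a YAML file
#'
#' @param cfg A `te_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_te_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "te_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Pre-set scale profiles
#'
#' Two named run scales: `"full"` is the full headline scale (N = 10^4,
#' 100 replicates, 10^4 generations), `"desk"` a scaled-down profile
#' (N = 2000, 20 replicates, 10^4 generations) for interactive work and
#' tests.  All other parameters keep their [te_config()] defaults and can be
#' overridden through `...`.
#'
#' @param profile `"full"` or `"desk"`.
#' @param ... Overrides forwarded to [te_config()].
#' @return A validated `te_config`.
#' @export
te_profile <- function(profile = c("desk", "full"), ...) {
  profile <- match.arg(profile)
  base <- switch(profile,
    full = list(N = 10000L, replicates = 100L, max_generations = 10000L),
    desk  = list(N = 2000L, replicates = 20L, max_generations = 10000L)
  )
  do.call(te_config, utils::modifyList(base, list(...)))
}

#' @export
print.te_config <- function(x, ...) {
  cat("<te_config>\n")
  cat(sprintf("  N = %d, u = %g, s = %g, r = %g, mode = %s\n",
              x$N, x$u, x$s, x$r, x$fitness_mode))
  cat(sprintf("  silencing: a = %g, b = %g, k = %g\n", x$a, x$b, x$k))
  if (x$modifier_direction != "none")
    cat(sprintf("  modifier: %s at (chr %d, %.0f), init freq %.3f\n",
                x$modifier_direction, x$modifier_chrom, x$modifier_pos,
                x$modifier_init_freq))
  if (x$r_e > 0)
    cat(sprintf("  ectopic: r_e = %g, suppression %s (T = %g)\n",
                x$r_e, if (x$ectopic_suppression) "on" else "off", x$T))
  cat(sprintf("  genome: %d x %.0f bp; n0 = %d; %d generations max; seed %d\n",
              x$n_chroms, x$chrom_length, x$n0, x$max_generations, x$seed))
  invisible(x)
}
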