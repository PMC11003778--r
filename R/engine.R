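## Wright-Fisher engine: one selection-reproduction-silencing-transposition
## cycle per generation, and full replicate runs.  The per-generation loop
## is native code; these wrappers manage seeds, population objects and
## trajectory records.

pop_to_parts <- function(pop) {
  list(ins = pop$ins, sex = as.integer(pop$sex), mod = pop$mod,
       fitness = as.numeric(pop$fitness), generation = pop$generation)
}

parts_to_pop <- function(parts) {
  new_te_population(parts$ins, parts$sex, parts$mod, parts$fitness,
                    generation = parts$generation)
}

#' Sample parent pairs for the next generation
#'
#' For each of N offspring, a mother is drawn from the females with
#' probability proportional to fitness and a father from the males likewise,
#' independently and with replacement (random mating).
#'
#' @param pop A `te_population` whose `fitness` slot is filled.
#' @param n Number of offspring (defaults to the census size).
#' @return Integer matrix `n x 2` with columns `mother`, `father`
#'   (individual indices).
#' @export
select_parents <- function(pop, n = population_size(pop)) {
  W <- pop$fitness
  if (anyNA(W)) stop("population fitness must be evaluated before parent sampling")
  females <- which(pop$sex == 0L)
  males <- which(pop$sex == 1L)
  if (length(females) == 0L || sum(W[females]) <= 0)
    stop_extinct("no viable female parent")
  if (length(males) == 0L || sum(W[males]) <= 0)
    stop_extinct("no viable male parent")
  mothers <- females[sample.int(length(females), n, replace = TRUE,
                                prob = W[females])]
  fathers <- males[sample.int(length(males), n, replace = TRUE,
                              prob = W[males])]
  cbind(mother = mothers, father = fathers)
}

stop_extinct <- function(msg) {
  stop(structure(class = c("tesim_extinction_error", "error", "condition"),
                 list(message = paste0("population extinct: ", msg), call = NULL)))
}

#' Apply one round of transposition to an individual
#'
#' Each existing copy duplicates independently with probability
#' `u_i' = max(0, u (1 - k M_i))` (`u` when `k = 0`); each new copy lands at
#' a uniformly random (chromosome, position, homolog) site not already
#' occupied on that homolog (collisions are resampled).  Newborn copies do
#' not transpose within the generation of their birth.
#'
#' @param individual A `te_individual` or insertion matrix.
#' @param cfg A [te_config()].
#' @param M Per-copy silencing magnitudes (required when `cfg$k > 0`).
#' @return The insertion matrix after transposition.
#' @export
transpose_genome <- function(individual, cfg, M = NULL) {
  cfg <- validate_te_config(cfg)
  ins <- if (inherits(individual, "te_individual")) individual$ins
         else as_ins_matrix(individual)
  n <- nrow(ins)
  if (cfg$k > 0) {
    if (is.null(M)) stop("per-copy silencing magnitudes `M` are required when k > 0")
    if (length(M) != n) stop("length(M) must equal the copy number")
    u_i <- effective_transposition_rate(cfg$u, cfg$k, M)
  } else {
    u_i <- rep(cfg$u, n)
  }
  out <- cpp_transpose_genome(cfg, ins, as.numeric(u_i))
  colnames(out) <- c("chrom", "pos", "homolog")
  out
}

#' Advance a population by one generation
#'
#' Runs the full cycle: fitness-weighted parent sampling, gamete formation
#' with recombination, union of gametes into offspring (modifier alleles
#' transmitted with their chromosome segment), per-offspring silencing draw,
#' transposition, ectopic-recombination viability and fitness evaluation.
#' If the input population's fitness slot is unset it is evaluated first
#' (with a fresh silencing draw).
#'
#' @param pop A `te_population`.
#' @param cfg A [te_config()].
#' @return The next-generation `te_population` (fitness evaluated).
#' @export
step_generation <- function(pop, cfg) {
  cfg <- validate_te_config(cfg)
  res <- cpp_run_simulation(cfg, pop_to_parts(pop), 1L, 1L, TRUE)
  if (res$status == "extinct") stop_extinct("all fitness zero in one sex")
  parts_to_pop(res$final_population)
}

#' Run one replicate simulation
#'
#' Iterates [step_generation()] natively until `generations` generations
#' have been simulated, or until the mean TE copy number reaches zero
#' (status `"te_loss"`), the population mean fitness falls below 0.1%
#' (status `"population_crash"`), or one sex has no individual with positive
#' fitness (status `"extinct"`).
#'
#' @param cfg A [te_config()].
#' @param generations Number of generations (default `cfg$max_generations`).
#' @param population Optional starting `te_population`; by default a fresh
#'   population is initialized per [init_population()].
#' @param seed Integer seed; defaults to `cfg$seed`. Pass `NA` to continue
#'   the current random stream (used by experiment drivers).
#' @param return_population If `TRUE`, the final population is returned
#'   (needed to chain phases).
#' @return A list of class `"te_run"`:
#'   \item{trajectory}{Data frame with one row per recorded generation:
#'     `generation`, `mean_copy_number`, `mean_fitness`,
#'     `modifier_frequency`.}
#'   \item{status}{`"completed"`, `"te_loss"`, `"population_crash"` or
#'     `"extinct"`.}
#'   \item{generations_run}{Last simulated generation.}
#'   \item{final_population}{`te_population` or `NULL`.}
#' @export
#' @examples
#' cfg <- te_config(N = 50, u = 0, s = 0, n0 = 5, max_generations = 20,
#'                  seed = 42)
#' run <- run_simulation(cfg)
#' tail(run$trajectory, 3)
run_simulation <- function(cfg, generations = cfg$max_generations,
                           population = NULL, seed = cfg$seed,
                           return_population = FALSE) {
  cfg <- validate_te_config(cfg)
  if (!is.na(seed)) set.seed(seed)
  parts <- if (is.null(population)) NULL else pop_to_parts(population)
  res <- cpp_run_simulation(cfg, parts, as.integer(generations),
                            cfg$record_stride, isTRUE(return_population))
  traj <- as.data.frame(res$trajectory)
  names(traj) <- c("generation", "mean_copy_number", "mean_fitness",
                   "modifier_frequency")
  out <- list(trajectory = traj, status = res$status,
              generations_run = res$generations_run,
              final_population = if (isTRUE(return_population))
                parts_to_pop(res$final_population) else NULL)
  class(out) <- "te_run"
  out
}

#' @export
print.te_run <- function(x, ...) {
  last <- x$trajectory[nrow(x$trajectory), ]
  cat(sprintf("<te_run> %s after %d generations\n", x$status, x$generations_run))
  cat(sprintf("  final mean copy number %.2f, mean fitness %.4f\n",
              last$mean_copy_number, last$mean_fitness))
  invisible(x)
}

#' Run replicate simulations of one configuration
#'
#' @param cfg A [te_config()]; `cfg$replicates` controls the count unless
#'   `replicates` is given.
#' @param replicates Number of replicates.
#' @param seeds Optional integer vector of per-replicate seeds (defaults to
#'   a deterministic derivation from `cfg$seed`, see [derive_seed()]).
#' @param generations Generations per replicate.
#' @return List of `te_run` objects.
#' @export
run_replicates <- function(cfg, replicates = cfg$replicates, seeds = NULL,
                           generations = cfg$max_generations) {
  cfg <- validate_te_config(cfg)
  if (is.null(seeds)) seeds <- derive_seed(cfg$seed, 0L, seq_len(replicates))
  stopifnot(length(seeds) == replicates)
  lapply(seq_len(replicates), function(i)
    run_simulation(cfg, generations = generations, seed = seeds[i]))
}
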