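## Modifier alleles of TE epigenetic silencing and the burn-in/invasion
## protocol.
##
## A single biallelic locus rescales the silencing parameter a in its
## carriers, semi-dominantly: a' = a (1 + 0.5 H) for an enhancing allele and
## a' = a (1 - 0.5 H) for a weakening allele, with dosage H = 0.5 in
## heterozygotes and 1 in homozygotes.

#' Modifier dosage
#'
#' Maps modifier genotype to the semi-dominant dosage `H`.
#'
#' @param x A `te_individual`, or an integer vector of modifier copy counts
#'   in `{0, 1, 2}`.
#' @return `H` in `{0, 0.5, 1}` (vectorized over copy counts).
#' @export
modifier_dosage <- function(x) {
  copies <- if (inherits(x, "te_individual")) x$modifier_copies else x
  if (any(!copies %in% 0:2)) stop("modifier copy counts must be 0, 1 or 2")
  copies / 2
}

#' Effective silencing scale under a modifier genotype
#'
#' @param a Baseline silencing scale.
#' @param direction `"enhance"`, `"weaken"` or `"none"`.
#' @param H Modifier dosage in `{0, 0.5, 1}` (vectorized).
#' @return `a * (1 + 0.5 H)` for an enhancer, `a * (1 - 0.5 H)` for a
#'   weakener, `a` otherwise.
#' @export
#' @examples
#' effective_silencing_parameter(0.02, "enhance", 1)  # 0.03
#' effective_silencing_parameter(0.02, "weaken", 1)   # 0.01
effective_silencing_parameter <- function(a, direction, H) {
  stopifnot(a > 0, all(H >= 0 & H <= 1))
  switch(direction,
    enhance = a * (1 + 0.5 * H),
    weaken  = a * (1 - 0.5 * H),
    none    = rep_len(a, length(H)) * 1,
    stop("unknown modifier direction: ", direction)
  )
}

#' Introduce a modifier allele into a population
#'
#' Places `round(2 N f)` allele copies (at least one) in randomly sampled
#' individuals, one copy each on a random homolog, so every initial carrier
#' is a heterozygote; if the copy budget exceeds N, the surplus is placed as
#' second copies in randomly chosen carriers.
#'
#' @param pop A `te_population` (typically the end of a burn-in phase).
#' @param cfg A [te_config()]; uses `modifier_init_freq`.
#' @return The population with modifier alleles assigned.
#' @export
introduce_modifier <- function(pop, cfg) {
  cfg <- validate_te_config(cfg)
  N <- population_size(pop)
  copies <- round(2 * N * cfg$modifier_init_freq)
  if (copies < 1)
    stop_config("modifier_init_freq",
                sprintf("frequency %g yields no allele copy at N = %d",
                        cfg$modifier_init_freq, N))
  if (copies > 2 * N)
    stop_config("modifier_init_freq", "frequency exceeds 1")
  mod <- matrix(0L, nrow = N, ncol = 2L)
  first <- sample.int(N, size = min(copies, N))
  mod[cbind(first, sample(c(1L, 2L), length(first), replace = TRUE))] <- 1L
  extra <- copies - N
  if (extra > 0L) {
    second <- sample(first, size = extra)
    for (i in second) mod[i, which(mod[i, ] == 0L)[1L]] <- 1L
  }
  pop$mod <- mod
  pop
}

#' Run a burn-in + modifier-invasion experiment
#'
#' Simulates `burn_in_generations` without the modifier so the TE copy
#' number can settle, introduces the modifier allele at frequency
#' `modifier_init_freq` (generation 1 of the invasion phase), then continues
#' for `invasion_generations`.  Carriers' silencing scale follows
#' [effective_silencing_parameter()] with the configured direction.
#'
#' @param cfg A [te_config()] with `modifier_direction` not `"none"`.
#' @param seed Optional integer overriding `cfg$seed`.
#' @return A list of class `"te_invasion"`:
#'   \item{trajectory}{Data frame over both phases with a `phase` column
#'     (`"pre_invasion"`/`"invasion"`).}
#'   \item{final_frequency}{Modifier allele frequency at the end.}
#'   \item{fixation_status}{`"fixed"`, `"lost"` or `"segregating"`.}
#'   \item{status}{Terminal run status (see [run_simulation()]).}
#'   \item{final_population}{The final `te_population`.}
#' @export
run_invasion_experiment <- function(cfg, seed = NULL) {
  cfg <- validate_te_config(cfg)
  if (cfg$modifier_direction == "none")
    stop_config("modifier_direction", "an invasion experiment needs a modifier direction")
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  set.seed(cfg$seed)

  burn_cfg <- cfg
  burn_cfg$modifier_direction <- "none"
  burn <- run_simulation(burn_cfg, generations = cfg$burn_in_generations,
                         seed = NA, return_population = TRUE)
  pre <- burn$trajectory
  pre$phase <- "pre_invasion"
  if (burn$status != "completed") {
    return(structure(list(trajectory = pre, final_frequency = 0,
                          fixation_status = "aborted", status = burn$status,
                          final_population = burn$final_population),
                     class = "te_invasion"))
  }

  pop <- introduce_modifier(burn$final_population, cfg)
  pop$fitness <- rep(NA_real_, population_size(pop))  # re-evaluate under modifier
  inv <- run_simulation(cfg, generations = cfg$invasion_generations,
                        population = pop, seed = NA, return_population = TRUE)
  post <- inv$trajectory   # generations continue from the burn-in counter
  post$phase <- "invasion"
  freq <- inv$trajectory$modifier_frequency[nrow(inv$trajectory)]
  status <- if (freq >= 1) "fixed" else if (freq <= 0) "lost" else "segregating"
  structure(list(trajectory = rbind(pre, post),
                 final_frequency = freq,
                 fixation_status = status,
                 status = inv$status,
                 final_population = inv$final_population),
            class = "te_invasion")
}

#' @export
print.te_invasion <- function(x, ...) {
  cat(sprintf("<te_invasion> %s (run status: %s)\n", x$fixation_status, x$status))
  cat(sprintf("  final modifier frequency %.4f after %d generations\n",
              x$final_frequency, max(x$trajectory$generation)))
  invisible(x)
}
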