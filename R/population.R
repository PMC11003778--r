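## Population and individual containers.
##
## A population is stored column-wise: one insertion matrix per individual
## (rows = TE copies, columns chrom/pos/homolog, all 0-based integers),
## plus parallel vectors for sex, modifier alleles and cached fitness.
## This is the exact shape exchanged with the native engine, so granular R
## operations and full-speed runs see the same state.

new_te_population <- function(ins, sex, mod, fitness = rep(NA_real_, length(ins)),
                              generation = 0L) {
  structure(list(ins = ins, sex = sex, mod = mod,
                 fitness = fitness, generation = as.integer(generation)),
            class = "te_population")
}

empty_ins <- function() {
  matrix(integer(0), ncol = 3L, dimnames = list(NULL, c("chrom", "pos", "homolog")))
}

# Coerce to an integer chrom/pos/homolog matrix.  Row order is preserved:
# per-copy vectors (silencing magnitudes, transposition rates) align with
# rows, so reordering is left to the native engine's internal storage.
as_ins_matrix <- function(x) {
  if (is.null(x) || (is.matrix(x) && nrow(x) == 0L) || length(x) == 0L)
    return(empty_ins())
  matrix(as.integer(x), ncol = 3L,
         dimnames = list(NULL, c("chrom", "pos", "homolog")))
}

check_ins_matrix <- function(m, who = "individual") {
  if (nrow(m) == 0L) return(invisible(m))
  key <- paste(m[, 1L], m[, 2L], m[, 3L])
  if (anyDuplicated(key)) {
    bad <- key[duplicated(key)][1L]
    stop(sprintf("duplicate TE site (chrom pos homolog = %s) in %s", bad, who))
  }
  if (any(m[, 3L] < 0L | m[, 3L] > 1L)) stop("homolog index must be 0 or 1")
  invisible(m)
}

#' Number of individuals in a population
#' @param pop A `te_population`.
#' @return Integer census size.
#' @export
population_size <- function(pop) length(pop$ins)

#' Extract one individual from a population
#'
#' @param pop A `te_population`.
#' @param i Individual index in `1:population_size(pop)`.
#' @return A `te_individual`: list with elements `ins` (insertion matrix with
#'   columns chrom/pos/homolog, 0-based), `sex` (`"female"`/`"male"`),
#'   `modifier` (length-2 integer, allele presence per homolog at the
#'   modifier locus), `modifier_copies` (0, 1 or 2) and `fitness`.
#' @export
te_individual <- function(pop, i) {
  structure(list(ins = pop$ins[[i]],
                 sex = if (pop$sex[[i]] == 0L) "female" else "male",
                 modifier = pop$mod[i, ],
                 modifier_copies = sum(pop$mod[i, ]),
                 fitness = pop$fitness[[i]]),
            class = "te_individual")
}

#' Build a deterministic miniature population for tests and examples
#'
#' @param layouts List with one element per individual: an insertion matrix
#'   (or 3-column coercible object, columns chrom/pos/homolog, 0-based), or
#'   `NULL`/empty for a TE-free individual.
#' @param sex Character vector of `"female"`/`"male"` per individual
#'   (default: alternating female/male).
#' @param modifier_copies Integer vector in `{0, 1, 2}` per individual
#'   (default all 0). A single copy is placed on homolog 0.
#' @param generation Generation counter for the returned population.
#' @return A `te_population`.
#' @export
#' @examples
#' pop <- make_test_population(list(cbind(0, 100, 0), NULL))
#' copy_number(pop)
make_test_population <- function(layouts, sex = NULL, modifier_copies = NULL,
                                 generation = 0L) {
  n <- length(layouts)
  if (n < 1L) stop("need at least one individual layout")
  ins <- vector("list", n)
  for (i in seq_len(n)) {
    m <- as_ins_matrix(layouts[[i]])
    check_ins_matrix(m, who = sprintf("individual %d", i))
    ins[[i]] <- m
  }
  if (is.null(sex)) sex <- rep(c("female", "male"), length.out = n)
  if (length(sex) != n) stop("`sex` must have one entry per individual")
  sexi <- match(sex, c("female", "male")) - 1L
  if (anyNA(sexi)) stop("`sex` entries must be \"female\" or \"male\"")
  if (is.null(modifier_copies)) modifier_copies <- rep(0L, n)
  if (length(modifier_copies) != n || any(!modifier_copies %in% 0:2))
    stop("`modifier_copies` must be 0, 1 or 2 per individual")
  mod <- cbind(as.integer(modifier_copies >= 1L), as.integer(modifier_copies == 2L))
  new_te_population(ins, sexi, mod, generation = generation)
}

#' Initialize a population with randomly placed TE insertions
#'
#' Every individual receives exactly `cfg$n0` TE copies at distinct
#' (chromosome, position) sites drawn uniformly over the genome, each copy on
#' one homolog chosen uniformly.  Each individual's sex is Bernoulli(1/2)
#' (reproduction errors later if a sex happens to be absent); no individual
#' carries the modifier allele.
#'
#' @param cfg A [te_config()].
#' @param seed Optional integer; when given, seeds the random stream first.
#' @return A `te_population` at generation 0.
#' @export
init_population <- function(cfg, seed = NULL) {
  cfg <- validate_te_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_init_population(cfg)
  new_te_population(res$ins, res$sex, res$mod, res$fitness, generation = 0L)
}

#' Diploid TE copy number
#'
#' Total insertion count across all chromosomes and both homologs.
#'
#' @param x A `te_individual` or `te_population`.
#' @param ... Unused.
#' @return Integer (per individual for a population).
#' @export
copy_number <- function(x, ...) UseMethod("copy_number")

#' @export
copy_number.te_individual <- function(x, ...) nrow(x$ins)

#' @export
copy_number.te_population <- function(x, ...) {
  vapply(x$ins, nrow, integer(1))
}

#' @export
copy_number.matrix <- function(x, ...) nrow(as_ins_matrix(x))

#' Count heterozygous TE insertions
#'
#' An insertion is heterozygous when no insertion occupies the same
#' (chromosome, position) on the opposite homolog; a same-position pair on
#' both homologs is a homozygous site and contributes no heterozygous copy.
#'
#' @param x A `te_individual`, insertion matrix, or `te_population`.
#' @param ... Unused.
#' @return Integer count (per individual for a population).
#' @export
count_heterozygous <- function(x, ...) UseMethod("count_heterozygous")

count_het_matrix <- function(m) {
  if (nrow(m) == 0L) return(0L)
  site <- paste(m[, 1L], m[, 2L])
  sum(table(site) == 1L)
}

#' @export
count_heterozygous.te_individual <- function(x, ...) count_het_matrix(x$ins)

#' @export
count_heterozygous.matrix <- function(x, ...) count_het_matrix(as_ins_matrix(x))

#' @export
count_heterozygous.te_population <- function(x, ...) {
  vapply(x$ins, count_het_matrix, integer(1))
}

#' Modifier allele frequency in a population
#' @param pop A `te_population`.
#' @return Fraction of modifier alleles among `2 N` slots.
#' @export
modifier_frequency <- function(pop) {
  sum(pop$mod) / (2 * population_size(pop))
}

#' Population summary statistics
#'
#' The per-generation observables recorded in trajectories: mean diploid
#' copy number, mean fitness and modifier allele frequency.
#'
#' @param object A `te_population`.
#' @param ... Unused.
#' @return A one-row data frame.
#' @export
summary.te_population <- function(object, ...) {
  data.frame(generation = object$generation,
             mean_copy_number = mean(copy_number(object)),
             mean_fitness = mean(object$fitness),
             modifier_frequency = modifier_frequency(object))
}

#' @export
print.te_population <- function(x, ...) {
  n <- copy_number(x)
  cat(sprintf("<te_population> N = %d, generation %d\n",
              population_size(x), x$generation))
  cat(sprintf("  mean copy number %.2f (range %d-%d), modifier freq %.3f\n",
              mean(n), min(n), max(n), modifier_frequency(x)))
  invisible(x)
}

#' Form one recombinant gamete
#'
#' Per chromosome, the crossover count is Poisson(`r*chrom_length`) with
#' uniform breakpoints and no interference; the gamete copies alternating
#' segments starting from a uniformly chosen homolog, and chromosomes assort
#' independently.  The modifier allele travels with the segment containing
#' its locus.
#'
#' @param individual A `te_individual` (or insertion matrix, in which case
#'   `modifier` gives the per-homolog alleles).
#' @param cfg A [te_config()] (supplies `r`, genome geometry and the
#'   modifier locus).
#' @param modifier Length-2 integer vector overriding the individual's
#'   per-homolog modifier alleles.
#' @param method `"breakpoints"` draws explicit Poisson crossover positions;
#'   `"walk"` uses the engine's equivalent formulation that flips the active
#'   homolog between consecutive TE positions with the recombination
#'   fraction `(1 - exp(-2 r d)) / 2`.  Both sample the same gamete
#'   distribution; `"breakpoints"` is the literal reference.
#' @return List with `sites` (matrix, columns chrom/pos) and `modifier`
#'   (0/1 allele carried by the gamete).
#' @export
make_gamete <- function(individual, cfg, modifier = NULL,
                        method = c("breakpoints", "walk")) {
  cfg <- validate_te_config(cfg)
  method <- match.arg(method)
  if (inherits(individual, "te_individual")) {
    ins <- individual$ins
    if (is.null(modifier)) modifier <- individual$modifier
  } else {
    ins <- as_ins_matrix(individual)
    if (is.null(modifier)) modifier <- c(0L, 0L)
  }
  res <- cpp_make_gamete(cfg, ins, as.integer(modifier), method)
  colnames(res$sites) <- c("chrom", "pos")
  res
}
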