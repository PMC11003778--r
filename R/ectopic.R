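## Dominant-lethal ectopic recombination between heterozygous TE pairs.
##
## Each unordered pair of eligible heterozygous copies independently
## initiates an ectopic exchange with probability r_e per generation; any
## event is dominant lethal (fitness 0).  With suppression on, a copy whose
## silencing magnitude exceeds the threshold T is shielded from ectopic
## exchange and drops out of the eligible set.

#' Count eligible heterozygous TE pairs
#'
#' Pairs are counted genome-wide among heterozygous insertions (see
#' [count_heterozygous()]).  When `cfg$ectopic_suppression` is `TRUE`, only
#' heterozygous copies with `M_i <= cfg$T` remain eligible.
#'
#' @param individual A `te_individual` or insertion matrix.
#' @param cfg A [te_config()] (uses `ectopic_suppression` and `T`).
#' @param M Per-copy silencing magnitudes aligned with the rows of the
#'   insertion matrix; required when suppression is on.
#' @return Integer: `h * (h - 1) / 2` with `h` the eligible heterozygous
#'   copy count.
#' @export
#' @examples
#' m <- cbind(0, c(100, 200, 300), 0)   # three unpaired copies
#' cfg <- te_config(N = 10, max_generations = 1)
#' eligible_heterozygous_pairs(m, cfg)  # choose(3, 2) = 3
eligible_heterozygous_pairs <- function(individual, cfg, M = NULL) {
  cfg <- validate_te_config(cfg)
  ins <- if (inherits(individual, "te_individual")) individual$ins
         else as_ins_matrix(individual)
  if (nrow(ins) == 0L) return(0L)
  site <- paste(ins[, 1L], ins[, 2L])
  het <- site %in% names(which(table(site) == 1L))
  if (cfg$ectopic_suppression) {
    if (is.null(M)) stop("silencing magnitudes `M` are required when suppression is on")
    if (length(M) != nrow(ins)) stop("length(M) must equal the copy number")
    het <- het & (M <= cfg$T)
  }
  h <- sum(het)
  as.integer(h * (h - 1L) / 2L)
}

#' Ectopic-recombination viability draw
#'
#' With `P` eligible pairs, the individual survives the generation's ectopic
#' hazard with probability `(1 - r_e)^P` (independent per-pair events); any
#' event is dominant lethal.
#'
#' @inheritParams eligible_heterozygous_pairs
#' @return Logical: `TRUE` if the individual remains viable.
#' @seealso [ectopic_inviability_probability()] for the deterministic rate.
#' @export
ectopic_viability <- function(individual, cfg, M = NULL) {
  cfg <- validate_te_config(cfg)
  if (cfg$r_e == 0) return(TRUE)
  P <- eligible_heterozygous_pairs(individual, cfg, M)
  stats::runif(1) <= (1 - cfg$r_e)^P
}

#' Probability of ectopic-recombination lethality
#'
#' Deterministic complement-power form `1 - (1 - r_e)^P` for `P` eligible
#' pairs.
#'
#' @param P Number of eligible heterozygous pairs (vectorized).
#' @param r_e Per-pair ectopic recombination probability.
#' @return Inviability probability in `[0, 1]`.
#' @export
ectopic_inviability_probability <- function(P, r_e) {
  stopifnot(all(P >= 0), r_e >= 0, r_e <= 1)
  1 - (1 - r_e)^P
}
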