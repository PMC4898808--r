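#' Propagation scenario for a germplasm-bank population
#'
#' Parameters of the multiplication history of a partially selfing population
#' maintained as a small germplasm accession: an initial heterozygosity `H0`
#' (operationally, the expected proportion of polymorphic loci), a founding
#' step that loses a fraction of heterozygosity through selfing (or halves it
#' for a single founder plant), and `t_total - 1` subsequent rounds of random
#' mating among `N` plants (`2N` chromosomes), each losing a fraction `1/2N`
#' of heterozygosity to drift.
#'
#' @param H0 initial heterozygosity, in `[0, 1]`.
#' @param s selfing rate, in `[0, 1]`.
#' @param single_plant was the accession founded from a single plant?
#' @param N plants per regeneration round.
#' @param t_total total rounds of multiplication (the founding step counts as
#'   the first round).
#' @param H_sample observed proportion of polymorphic loci at sampling
#'   (optional, used by inversion helpers).
#' @return A list of class `propagation_scenario`.
#' @export
propagation_scenario <- function(H0 = NA_real_, s = 1, single_plant = FALSE,
                                 N = 12L, t_total = 10L, H_sample = NA_real_) {
  if (!is.na(H0) && (H0 < 0 || H0 > 1)) stop("H0 must be in [0, 1]")
  if (s < 0 || s > 1) stop("selfing rate s must be in [0, 1]")
  if (N < 1L) stop("N must be >= 1")
  if (t_total < 1L) stop("t_total must be >= 1")
  structure(list(H0 = H0, s = s, single_plant = single_plant,
                 N = as.integer(N), t_total = as.integer(t_total),
                 H_sample = H_sample),
            class = "propagation_scenario")
}

#' Heterozygosity retained through the founding step
#'
#' A single founder plant propagated by selfing halves heterozygosity in the
#' first generation. If two or more plants are crossed to found the line, a
#' proportion `0.5 * s` of heterozygosity is lost through the selfing rate
#' `s`, retaining a factor `1 - 0.5 * s`.
#'
#' @param s selfing rate, in `[0, 1]`.
#' @param single_plant if `TRUE`, the factor is 0.5 regardless of `s`.
#' @return The retention factor in `(0, 1]`.
#' @examples
#' founder_factor(1)               # full selfing: 0.5
#' founder_factor(0)               # outcrossing founders: 1
#' founder_factor(0.5)             # 0.75
#' @export
founder_factor <- function(s, single_plant = FALSE) {
  if (single_plant) return(0.5)
  if (is.na(s) || s < 0 || s > 1) stop("founder_factor: s must be in [0, 1]")
  1 - 0.5 * s
}

#' Heterozygosity decay under random mating in a finite population
#'
#' Expected heterozygosity after `g` generations of Wright-Fisher random
#' mating among `two_N` chromosomes: each generation retains a fraction
#' `1 - 1/two_N`.
#'
#' @param H current heterozygosity, in `[0, 1]`.
#' @param two_N number of chromosomes (`2N`), at least 2.
#' @param g number of generations, `>= 0`.
#' @return `H * (1 - 1/two_N)^g`.
#' @examples
#' decay_heterozygosity(0.5, two_N = 24, g = 1)  # 0.5 * 23/24
#' @export
decay_heterozygosity <- function(H, two_N, g) {
  if (any(H < 0 | H > 1)) stop("decay_heterozygosity: H must be in [0, 1]")
  if (any(two_N < 2)) stop("decay_heterozygosity: two_N must be >= 2")
  if (any(g < 0)) stop("decay_heterozygosity: g must be >= 0")
  H * (1 - 1 / two_N)^g
}

#' Invert the decay model to the initial heterozygosity
#'
#' Given the proportion of polymorphic loci observed at sampling, the selfing
#' rate, the regeneration population size and the total number of
#' multiplication rounds, solves the forward model
#' `H_sample = H0 * f * (1 - 1/two_N)^(t_total - 1)` for `H0`, where `f` is
#' [founder_factor()]. The founding step is the first of the `t_total`
#' rounds, leaving `t_total - 1` random-mating rounds.
#'
#' @param H_sample observed proportion of polymorphic loci, in `(0, 1]`.
#' @param s selfing rate.
#' @param single_plant single founder plant?
#' @param two_N chromosomes per regeneration round.
#' @param t_total total rounds of multiplication.
#' @return The estimated `H0` (full precision). If the estimate exceeds 1 the
#'   scenario is infeasible and the attribute `infeasible` is set to `TRUE`.
#' @examples
#' round(invert_H0(13/220, s = 1, two_N = 24, t_total = 10), 2)  # 0.17
#' @export
invert_H0 <- function(H_sample, s = 1, single_plant = FALSE, two_N, t_total) {
  if (is.na(H_sample) || H_sample <= 0) stop("invert_H0: H_sample must be > 0")
  if (H_sample > 1) stop("invert_H0: H_sample must be <= 1")
  if (t_total < 1L) stop("invert_H0: t_total must be >= 1")
  f <- founder_factor(s, single_plant)
  H0 <- H_sample / (f * (1 - 1 / two_N)^(t_total - 1))
  attr(H0, "infeasible") <- H0 > 1
  H0
}

#' Forward Monte-Carlo simulation of the propagation history
#'
#' Validates the analytic decay recursion by simulating loci through the
#' multiplication history. Each locus is founded polymorphic (allele frequency
#' `p = 0.5`, a heterozygous founder) with probability `2 * H0`, so that the
#' founding expectation of the pairwise-difference heterozygosity `2 p (1-p)`
#' equals `H0` exactly. The founding step applies [founder_factor()] as a
#' deterministic expectation factor (the analytic model is itself an
#' expectation recursion); the remaining `t_total - 1` rounds are binomial
#' Wright-Fisher resamplings of `2N` chromosomes, each of which loses exactly
#' `1/2N` of expected heterozygosity.
#'
#' @param H0 initial heterozygosity, in `[0, 0.5]` (the heterozygous-founder
#'   initialization requires `2 * H0 <= 1`).
#' @param s selfing rate.
#' @param single_plant single founder plant?
#' @param N plants per regeneration round (`2N` chromosomes).
#' @param t_total total rounds (founding step plus `t_total - 1` matings).
#' @param n_loci loci per replicate.
#' @param n_replicates independent replicates.
#' @param seed optional RNG seed for reproducibility.
#' @return A list with `mean` (grand mean heterozygosity at sampling),
#'   `se` (Monte-Carlo standard error over replicates), `per_replicate`
#'   (replicate means) and `trajectory` (mean heterozygosity after the
#'   founding step and after each mating round; length `t_total`).
#' @export
simulate_propagation <- function(H0, s = 1, single_plant = FALSE, N = 12L,
                                 t_total = 10L, n_loci = 220L,
                                 n_replicates = 2000L, seed = NULL) {
  if (H0 < 0 || H0 > 0.5) {
    stop("simulate_propagation: H0 must be in [0, 0.5] for the heterozygous-founder initialization")
  }
  if (n_loci < 1L || n_replicates < 1L) stop("n_loci and n_replicates must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  f <- founder_factor(s, single_plant)
  two_N <- 2L * as.integer(N)
  m <- n_loci * n_replicates
  p <- 0.5 * stats::rbinom(m, 1L, min(2 * H0, 1))
  rep_id <- rep(seq_len(n_replicates), each = n_loci)
  traj <- numeric(t_total)
  traj[1L] <- f * mean(2 * p * (1 - p))
  if (t_total > 1L) {
    for (g in 2L:t_total) {
      p <- stats::rbinom(m, two_N, p) / two_N
      traj[g] <- f * mean(2 * p * (1 - p))
    }
  }
  het <- f * 2 * p * (1 - p)
  per_rep <- tapply(het, rep_id, mean)
  list(mean = mean(het),
       se = stats::sd(per_rep) / sqrt(n_replicates),
       per_replicate = as.numeric(per_rep),
       trajectory = traj)
}

#' Simulate allele-frequency trajectories of founding polymorphisms
#'
#' Per-locus stochastic counterpart of the expectation model, used by the
#' synthetic-data generator: a locus is founded polymorphic with probability
#' `H0` at frequency 0.5; the polymorphism survives the founding step with
#' probability [founder_factor()]; the remaining rounds are Wright-Fisher
#' binomial resamplings of `2N` chromosomes.
#'
#' @param n_loci number of loci.
#' @param scenario a [propagation_scenario] with `H0` set.
#' @return Numeric vector of final population allele frequencies (0 for loci
#'   that were never polymorphic or lost their polymorphism).
#' @keywords internal
simulate_locus_frequencies <- function(n_loci, scenario) {
  f <- founder_factor(scenario$s, scenario$single_plant)
  two_N <- 2L * scenario$N
  poly <- stats::rbinom(n_loci, 1L, scenario$H0) * stats::rbinom(n_loci, 1L, f)
  p <- 0.5 * poly
  if (scenario$t_total > 1L) {
    for (g in 2L:scenario$t_total) p <- stats::rbinom(n_loci, two_N, p) / two_N
  }
  p
}
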