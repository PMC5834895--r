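# Replicate simulation of the fecundity test: draws panels at the count
# level (no sequences) and runs the Spearman test of species-mean LoF
# proportion against lifetime fecundity. With coupling_beta = 0 this measures
# type-I error; with strong coupling it measures power.

#' Replicate the LoF-vs-fecundity Spearman test over simulated panels
#'
#' For each replicate, a fresh panel is drawn (fecundities, selection
#' coefficients, equilibrium frequencies), per-individual LoF gene counts are
#' sampled under Hardy-Weinberg via multinomial draws per individual
#' (homozygous with probability \eqn{q^2}, heterozygous with \eqn{2q(1-q)}),
#' species means of \eqn{p = (N_{het} + 2N_{hom})/(2N)} are formed, and the
#' single Spearman test against fecundity is run. No multiple-testing
#' correction is applied: one test per replicate.
#'
#' @param config an `lof_sim_config`; `coupling_beta = 0` gives the null.
#' @param n_reps number of replicate panels.
#' @param alpha rejection level on the raw p-value.
#' @param seed root seed for the replicate stream.
#' @return a data frame with one row per replicate (`rho`, `p`, `reject`);
#'   the rejection fraction is `mean(reject)`.
#' @export
simulate_trait_test <- function(config, n_reps = 1000L, alpha = 0.05,
                                seed = config$seed) {
  validate_sim_config(config)
  S <- config$n_species
  G <- config$genes_per_species
  n_ind <- config$individuals_per_species
  fr <- config$fecundity_range
  f_ref <- sqrt(fr[1] * fr[2])
  out <- data.frame(rho = numeric(n_reps), p = numeric(n_reps),
                    reject = logical(n_reps))
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    fec <- exp(stats::runif(S, log(fr[1]), log(fr[2])))
    s_i <- config$sel_coeff * (fec / f_ref)^config$coupling_beta
    q_i <- pmin(1, config$mu_lof_per_gene / s_i)
    # effective genes per individual after coverage dropout
    n_cov <- stats::rbinom(S * n_ind, G, 1 - config$coverage_dropout)
    qs <- rep(q_i, each = n_ind)
    n_hom <- stats::rbinom(S * n_ind, n_cov, qs^2)
    # P(het | not hom) = 2q(1-q)/(1-q^2) = 2q/(1+q), defined through q = 1
    n_het <- stats::rbinom(S * n_ind, n_cov - n_hom, 2 * qs / (1 + qs))
    p_ind <- lof_proportion(n_cov, n_het, n_hom)
    p_sp <- colMeans(matrix(p_ind, nrow = n_ind))
    st <- spearman_test(p_sp, fec)
    out$rho[r] <- st$rho
    out$p[r] <- st$p
    out$reject[r] <- !is.na(st$p) && st$p < alpha
  }
  out
}
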