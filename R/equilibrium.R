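# Deterministic mutation-selection balance arithmetic for a deleterious
# allele under heterozygous selection: equilibrium frequency q = u/s.

#' Equilibrium frequency of a deleterious allele
#'
#' Under recurrent mutation at rate u per gene per generation and
#' heterozygous selection coefficient s, the deterministic equilibrium allele
#' frequency is q = u/s (drift is negligible for s around 1% in populations
#' with effective size above ~1e4).
#'
#' @param u per-gene per-generation LoF mutation rate.
#' @param s heterozygous selection coefficient (> 0).
#' @return q = u/s (not clipped; callers decide how to treat q > 1).
#' @export
equilibrium_lof_freq <- function(u, s) {
  if (any(s <= 0) && any(u > 0))
    stop("equilibrium undefined for s <= 0 with u > 0")
  u / s
}

#' Mutation rate implied by an observed equilibrium frequency
#'
#' Inverts q = u/s: u = q s per gene; dividing by the gene length in
#' nucleotides gives the per-nucleotide rate. An observed hard-core LoF allele
#' frequency of 0.0022 with s = 0.01 implies u = 2.2e-5 per gene, i.e. about
#' 2e-8 per nucleotide for a 1000-nt gene.
#'
#' @param q observed allele frequency.
#' @param s heterozygous selection coefficient.
#' @param gene_length_nt optional gene length; when given, the per-nucleotide
#'   rate is returned instead of the per-gene rate.
#' @return implied mutation rate.
#' @export
implied_mutation_rate <- function(q, s, gene_length_nt = NULL) {
  u <- q * s
  if (is.null(gene_length_nt)) u else u / gene_length_nt
}
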