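# The per-individual LoF allele proportion p = (N_het + 2 N_hom) / (2N),
# species means, per-variant-type breakdowns and the min/max/mean summary.

#' LoF allele proportion
#'
#' \eqn{p = (N_{LoFHet} + 2 N_{LoFHom}) / (2N)} where N is the number of ORFs
#' fully sequenced for the individual (restricted to the gene set under
#' consideration), and the numerator counts gene alleles carrying at least one
#' LoF variant.
#'
#' @param n_total N, genes fully sequenced (vectorised).
#' @param n_het genes with a heterozygous LoF allele.
#' @param n_hom genes with a homozygous LoF allele.
#' @return fraction in \[0, 1\]; `NA` when `n_total` is 0 (undefined, distinct
#'   from an observed 0).
#' @export
lof_proportion <- function(n_total, n_het, n_hom) {
  stopifnot(length(n_het) == length(n_total),
            length(n_hom) == length(n_total))
  if (any(n_het + n_hom > n_total, na.rm = TRUE))
    stop("n_het + n_hom cannot exceed n_total")
  ifelse(n_total > 0, (n_het + 2 * n_hom) / (2 * n_total), NA_real_)
}

LOF_TYPE_MAP <- c(all_lof = NA, nonsense = "stopgain",
                  frameshift = "frameshift", stoploss = "stoploss")

#' Per-individual LoF statistics over gene sets, variant types and regions
#'
#' Restricts both the denominator N and the LoF gene counts to the genes of
#' the chosen set that are fully sequenced in this individual. For
#' `region = "last100nt"` only variants inside the terminal CDS window count
#' as LoF (N is unchanged). For a specific variant type, a gene counts if its
#' LoF variants include that type (a gene with both a nonsense and a
#' frameshift variant counts in both type-specific statistics).
#'
#' @param variants the individual's classified LoF variant table
#'   (`transcript_id`, `zygosity`, `class`, `in_last100`); non-LoF rows are
#'   ignored.
#' @param covered character vector: gene IDs fully sequenced in this
#'   individual.
#' @param partition named list of gene-ID vectors, e.g.
#'   `list(all = ..., core = ..., hardcore = ...)`.
#' @param gene_sets,variant_types,regions which combinations to compute.
#' @return data frame with one row per (gene_set, variant_type, region):
#'   `n_total`, `n_het`, `n_hom`, `p` (`NA` when the restricted set is empty).
#' @export
individual_statistics <- function(variants, covered, partition,
                                  gene_sets = names(partition),
                                  variant_types = names(LOF_TYPE_MAP),
                                  regions = c("full_cds", "last100nt")) {
  lofv <- variants[is_lof(variants$class), , drop = FALSE]
  out <- list()
  for (gs in gene_sets) {
    genes <- intersect(partition[[gs]], covered)
    n_tot <- length(genes)
    gv <- lofv[lofv$transcript_id %in% genes, , drop = FALSE]
    for (reg in regions) {
      rv <- if (reg == "last100nt") gv[gv$in_last100, , drop = FALSE] else gv
      for (vt in variant_types) {
        tv <- if (is.na(LOF_TYPE_MAP[[vt]])) rv
              else rv[rv$class == LOF_TYPE_MAP[[vt]], , drop = FALSE]
        if (nrow(tv)) {
          st <- vapply(split(tv$zygosity, tv$transcript_id),
                       function(z) if (any(z == "hom")) 2L else 1L,
                       integer(1))
          n_hom <- sum(st == 2L)
          n_het <- sum(st == 1L)
        } else n_hom <- n_het <- 0L
        out[[length(out) + 1L]] <- data.frame(
          gene_set = gs, variant_type = vt, region = reg,
          n_total = n_tot, n_het = n_het, n_hom = n_hom,
          p = if (n_tot > 0) lof_proportion(n_tot, n_het, n_hom) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Species means of per-individual proportions
#'
#' Unweighted arithmetic mean over an individual's proportions within each
#' species, for every (gene_set, variant_type, region) cell; missing
#' individual values (empty restricted set) propagate as missing, never as 0.
#'
#' @param per_individual data frame with `species_id`, `individual_id`,
#'   `gene_set`, `variant_type`, `region`, `p`.
#' @return data frame with `species_id`, `gene_set`, `variant_type`, `region`,
#'   `n_individuals`, `mean_p`.
#' @export
species_means <- function(per_individual) {
  key <- interaction(per_individual$species_id, per_individual$gene_set,
                     per_individual$variant_type, per_individual$region,
                     drop = TRUE)
  rows <- lapply(split(per_individual, key), function(d) {
    data.frame(species_id = d$species_id[1], gene_set = d$gene_set[1],
               variant_type = d$variant_type[1], region = d$region[1],
               n_individuals = nrow(d),
               mean_p = if (all(is.na(d$p))) NA_real_
                        else mean(d$p, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$species_id, out$gene_set, out$variant_type, out$region), ]
}

#' Min/max/mean summary across species
#'
#' One row per variant type (for a chosen gene set and region): the minimum,
#' maximum and mean of the species-mean proportions, in percent rounded to two
#' decimals.
#'
#' @param species_table output of [species_means()].
#' @param gene_set,region which slice to summarise (default: all genes, full
#'   CDS — the headline table).
#' @return data frame `variant_type`, `min_pct`, `max_pct`, `mean_pct`.
#' @export
summary_table <- function(species_table, gene_set = "all",
                          region = "full_cds") {
  d <- species_table[species_table$gene_set == gene_set &
                       species_table$region == region, , drop = FALSE]
  rows <- lapply(split(d, d$variant_type), function(x) {
    v <- x$mean_p[!is.na(x$mean_p)] * 100
    data.frame(variant_type = x$variant_type[1],
               min_pct = round(min(v), 2), max_pct = round(max(v), 2),
               mean_pct = round(mean(v), 2), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- match(c("all_lof", "nonsense", "frameshift", "stoploss"),
               out$variant_type)
  out <- out[ord[!is.na(ord)], ]
  rownames(out) <- NULL
  out
}
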