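# Site-, individual- and species-level exclusion rules, and the core /
# hard-core gene set construction.

#' Site-level validity thresholds
#'
#' A valid position needs depth strictly above `min_depth_exclusive` and both
#' variant-calling and mapping quality strictly above the quality floors
#' ("more than 5x", "over 20" read literally as strict inequalities). The
#' `strict20x` preset raises the depth rule to at-least-20x (i.e. depth > 19),
#' the robustness mode used to check that results do not hinge on marginal
#' calls.
#'
#' @param min_depth_exclusive reads; sites must exceed this.
#' @param min_qual_exclusive phred floor for variant-calling quality.
#' @param min_mapq_exclusive phred floor for mapping quality.
#' @param preset `"default"` or `"strict20x"`.
#' @return a list of class `site_thresholds`.
#' @export
site_thresholds <- function(min_depth_exclusive = 5,
                            min_qual_exclusive = 20,
                            min_mapq_exclusive = 20,
                            preset = c("default", "strict20x")) {
  preset <- match.arg(preset)
  if (preset == "strict20x") min_depth_exclusive <- 19
  stopifnot(min_depth_exclusive >= 0, min_qual_exclusive >= 0,
            min_mapq_exclusive >= 0)
  structure(list(min_depth_exclusive = min_depth_exclusive,
                 min_qual_exclusive = min_qual_exclusive,
                 min_mapq_exclusive = min_mapq_exclusive,
                 preset = preset),
            class = "site_thresholds")
}

#' Filter variant calls on depth and quality
#'
#' Keeps calls with `depth > min_depth_exclusive`,
#' `variant_qual > min_qual_exclusive` and `mapping_qual > min_mapq_exclusive`
#' (all strict). A call exactly at a floor (e.g. depth 5) is removed.
#'
#' @param calls data frame with `depth`, `variant_qual`, `mapping_qual`.
#' @param thresholds a [site_thresholds()] object.
#' @return the kept subset, row order preserved.
#' @export
filter_variant_calls <- function(calls, thresholds = site_thresholds()) {
  if (is.null(calls) || nrow(calls) == 0L) return(calls)
  keep <- calls$depth > thresholds$min_depth_exclusive &
    calls$variant_qual > thresholds$min_qual_exclusive &
    calls$mapping_qual > thresholds$min_mapq_exclusive
  calls[keep, , drop = FALSE]
}

#' Genes whose whole CDS passes the depth floor
#'
#' "Fully sequenced" is read strictly: every CDS position must exceed the site
#' depth floor. These genes form N, the denominator of the per-individual LoF
#' proportion.
#'
#' @param depth_tracks named list (by transcript ID) of per-position integer
#'   depth vectors covering each transcript.
#' @param orfs ORF table ([annotate_orfs()]).
#' @param thresholds a [site_thresholds()] object.
#' @return character vector of qualifying transcript IDs.
#' @export
fully_sequenced_orfs <- function(depth_tracks, orfs,
                                 thresholds = site_thresholds()) {
  ok <- vapply(seq_len(nrow(orfs)), function(i) {
    tr <- depth_tracks[[orfs$transcript_id[i]]]
    if (is.null(tr) || length(tr) < orfs$cds_end[i]) return(FALSE)
    all(tr[orfs$cds_start[i]:orfs$cds_end[i]] >
          thresholds$min_depth_exclusive)
  }, logical(1))
  orfs$transcript_id[ok]
}

#' Individual-level exclusion
#'
#' Individuals with mean coverage below 10x, read alignment rate below 80%,
#' fewer than 5000 (at least partially) covered ORFs, or fewer than 100
#' covered core genes are excluded; "below" excludes, so boundary values are
#' kept.
#'
#' @param profiles data frame with `individual_id`, `mean_coverage`,
#'   `alignment_rate`, `n_covered_orfs`, `n_covered_core`.
#' @param min_coverage,min_alignment_rate,min_orfs,min_core inclusive floors.
#' @return list with `kept` (subset of profiles) and `log` (data frame
#'   `level`, `id`, `failed_criterion`, `value`, `threshold`).
#' @export
filter_individuals <- function(profiles, min_coverage = 10,
                               min_alignment_rate = 0.80,
                               min_orfs = 5000, min_core = 100) {
  log <- exclusion_log_frame()
  fail <- function(id, crit, value, thr) {
    data.frame(level = "individual", id = id, failed_criterion = crit,
               value = value, threshold = thr, stringsAsFactors = FALSE)
  }
  keep <- logical(nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    p <- profiles[i, ]
    if (p$mean_coverage < min_coverage) {
      log <- rbind(log, fail(p$individual_id, "coverage", p$mean_coverage,
                             min_coverage))
    } else if (p$alignment_rate < min_alignment_rate) {
      log <- rbind(log, fail(p$individual_id, "alignment_rate",
                             p$alignment_rate, min_alignment_rate))
    } else if (p$n_covered_orfs < min_orfs) {
      log <- rbind(log, fail(p$individual_id, "covered_orfs",
                             p$n_covered_orfs, min_orfs))
    } else if (p$n_covered_core < min_core) {
      log <- rbind(log, fail(p$individual_id, "covered_core",
                             p$n_covered_core, min_core))
    } else keep[i] <- TRUE
  }
  list(kept = profiles[keep, , drop = FALSE], log = log)
}

exclusion_log_frame <- function() {
  data.frame(level = character(), id = character(),
             failed_criterion = character(), value = numeric(),
             threshold = numeric(), stringsAsFactors = FALSE)
}

#' Species-level exclusion
#'
#' Species with read alignment rates below 70%, fewer than 5000 predicted
#' ORFs, or fewer than 100 predicted core genes are excluded, as are
#' haplodiploid species (haploid males expose recessive alleles to selection
#' differently, so they are not comparable). Boundary values are kept.
#'
#' @param stats data frame with `species_id`, `alignment_rate`, `n_orfs`,
#'   `n_core`, `haplodiploid`.
#' @param min_alignment_rate,min_orfs,min_core inclusive floors.
#' @return list with `kept` and `log` as in [filter_individuals()].
#' @export
filter_species <- function(stats, min_alignment_rate = 0.70,
                           min_orfs = 5000, min_core = 100) {
  log <- exclusion_log_frame()
  fail <- function(id, crit, value, thr) {
    data.frame(level = "species", id = id, failed_criterion = crit,
               value = value, threshold = thr, stringsAsFactors = FALSE)
  }
  keep <- logical(nrow(stats))
  for (i in seq_len(nrow(stats))) {
    s <- stats[i, ]
    if (s$alignment_rate < min_alignment_rate) {
      log <- rbind(log, fail(s$species_id, "alignment_rate",
                             s$alignment_rate, min_alignment_rate))
    } else if (s$n_orfs < min_orfs) {
      log <- rbind(log, fail(s$species_id, "predicted_orfs", s$n_orfs,
                             min_orfs))
    } else if (s$n_core < min_core) {
      log <- rbind(log, fail(s$species_id, "core_genes", s$n_core, min_core))
    } else if (isTRUE(s$haplodiploid)) {
      log <- rbind(log, fail(s$species_id, "haplodiploid", 1, 0))
    } else keep[i] <- TRUE
  }
  list(kept = stats[keep, , drop = FALSE], log = log)
}

#' Core gene set
#'
#' Genes present in the provided essential-gene catalogue (shared ID
#' namespace; ortholog mapping happens upstream or in the generator).
#'
#' @param all_genes character vector of gene IDs.
#' @param essential_ids character vector of essential gene IDs.
#' @return character vector (intersection), in `all_genes` order.
#' @export
build_core_set <- function(all_genes, essential_ids) {
  if (length(essential_ids) == 0L)
    warning("empty essential-gene list: core set is empty")
  all_genes[all_genes %in% essential_ids]
}

#' Hard-core gene set
#'
#' Core genes carrying no homozygous LoF allele in any individual of any
#' species; one homozygote anywhere in the panel removes the gene for all
#' species.
#'
#' @param core character vector of core gene IDs.
#' @param zygosities_by_species list (by species) of data frames with
#'   `gene_id`, `state` (`"hom_lof"` / `"het_lof"` / `"none"`), one row per
#'   gene-individual observation.
#' @return character vector of hard-core gene IDs (subset of `core`).
#' @export
build_hardcore_set <- function(core, zygosities_by_species) {
  hom <- unique(unlist(lapply(zygosities_by_species, function(z) {
    if (is.null(z) || nrow(z) == 0L) character(0)
    else unique(z$gene_id[z$state == "hom_lof"])
  })))
  setdiff(core, hom)
}
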