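# End-to-end orchestration: simulate -> annotate -> filter -> score ->
# correlate, with deterministic outputs and a machine-readable manifest.

rbind_all <- function(lst) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (!length(lst)) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full LoF prevalence pipeline
#'
#' Either simulates a panel (from `config`) or ingests an existing directory
#' (`input_dir`), then: predicts ORFs (longest complete ORF per transcript, at
#' least 100 aa), applies site / individual / species exclusion rules,
#' classifies variants, collapses per-gene LoF alleles, computes per-individual
#' and species-mean proportions for all / core / hard-core genes, the
#' min-max-mean summary, and the Spearman/BH correlation grid against
#' life-history traits.
#'
#' Modes: `"default"` (site depth > 5, full CDS), `"strict20x"` (site depth at
#' least 20), `"last100nt"` (only LoF variants in the terminal 100 nt of each
#' CDS count, a proxy for the NMD-escaping last exon).
#'
#' @param out_dir output directory; all tables and the manifest land here.
#' @param config an `lof_sim_config` to simulate inputs (exclusive with
#'   `input_dir`).
#' @param input_dir an existing panel directory (see [read_species_inputs()]).
#' @param mode analysis mode, see above.
#' @param min_protein_aa ORF length floor in amino acids.
#' @param species_floors named list overriding [filter_species()] floors
#'   (`min_alignment_rate`, `min_orfs`, `min_core`); defaults are the
#'   analysis values (0.70, 5000, 100). Lower them for small test panels.
#' @param individual_floors named list overriding [filter_individuals()]
#'   floors (`min_coverage`, `min_alignment_rate`, `min_orfs`, `min_core`);
#'   defaults 10x, 0.80, 5000, 100.
#' @param log_level `"info"` prints per-stage record counts; `"quiet"` doesn't.
#' @return (invisibly) a list with every intermediate table, the output file
#'   manifest and the seed.
#' @export
run_pipeline <- function(out_dir, config = NULL, input_dir = NULL,
                         mode = c("default", "strict20x", "last100nt"),
                         min_protein_aa = 100L,
                         species_floors = list(),
                         individual_floors = list(),
                         log_level = c("info", "quiet")) {
  mode <- match.arg(mode)
  log_level <- match.arg(log_level)
  say <- function(...) if (log_level == "info") message(sprintf(...))
  if (is.null(config) == is.null(input_dir))
    stop("exactly one of 'config' or 'input_dir' must be given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config)) {
    input_dir <- file.path(out_dir, "inputs")
    stage("simulate", {
      panel <- build_species_panel(config)
      geno <- sample_individual_genotypes(panel)
      write_panel(panel, geno, input_dir)
      say("simulate: %d species, %d genes each, %d individuals",
          config$n_species, config$genes_per_species,
          nrow(geno$profiles))
    })
  }
  inputs <- stage("read", read_species_inputs(input_dir))
  seed <- if (!is.null(config)) config$seed else NA_integer_

  thresholds <- site_thresholds(
    preset = if (mode == "strict20x") "strict20x" else "default")
  region <- if (mode == "last100nt") "last100nt" else "full_cds"

  # -- annotate: longest complete ORF per transcript --------------------------
  orf_tables <- stage("annotate", {
    lapply(inputs$transcripts, annotate_orfs, min_protein_aa = min_protein_aa)
  })
  say("annotate: %d/%d transcripts with a qualifying ORF",
      sum(vapply(orf_tables, nrow, integer(1))),
      sum(lengths(inputs$transcripts)))

  # -- species-level QC -------------------------------------------------------
  core_ids <- inputs$core_ids
  sp_stats <- stage("filter_species", {
    d <- do.call(rbind, lapply(inputs$species_ids, function(sp) {
      prof <- inputs$profiles[inputs$profiles$species_id == sp, ]
      ot <- orf_tables[[sp]]
      data.frame(species_id = sp,
                 alignment_rate = mean(prof$alignment_rate),
                 n_orfs = nrow(ot),
                 n_core = sum(ot$transcript_id %in% core_ids),
                 haplodiploid =
                   inputs$traits$haplodiploid[inputs$traits$species_id == sp],
                 stringsAsFactors = FALSE)
    }))
    do.call(filter_species, c(list(d), species_floors))
  })
  kept_species <- sp_stats$kept$species_id
  say("filter: %d/%d species kept", length(kept_species),
      length(inputs$species_ids))

  # -- individual-level QC ----------------------------------------------------
  ind_filter <- stage("filter_individuals", {
    do.call(filter_individuals, c(
      list(inputs$profiles[inputs$profiles$species_id %in% kept_species, ]),
      individual_floors))
  })
  kept_inds <- ind_filter$kept$individual_id
  say("filter: %d/%d individuals kept", length(kept_inds),
      nrow(inputs$profiles))
  exclusion_log <- rbind(sp_stats$log, ind_filter$log)

  # -- classify variants, collapse gene alleles -------------------------------
  ann_list <- list()
  zyg_by_species <- list()
  covered_by_ind <- list()
  stage("classify", {
    for (sp in kept_species) {
      seqs <- inputs$transcripts[[sp]]
      ot <- orf_tables[[sp]]
      rownames(ot) <- ot$transcript_id
      prof <- ind_filter$kept[ind_filter$kept$species_id == sp, ]
      zyg_sp <- list()
      for (ind in prof$individual_id) {
        cov <- inputs$coverage[inputs$coverage$individual_id == ind, ]
        covered <- intersect(
          cov$gene_id[cov$min_cds_depth > thresholds$min_depth_exclusive],
          ot$transcript_id)
        covered_by_ind[[ind]] <- covered
        v <- filter_variant_calls(inputs$variants[[ind]], thresholds)
        if (nrow(v)) {
          parts <- lapply(split(v, v$transcript_id), function(vt) {
            tid <- vt$transcript_id[1]
            orf <- if (tid %in% rownames(ot)) ot[tid, ] else NULL
            classify_variants(orf, seqs[[tid]], vt)
          })
          av <- do.call(rbind, parts)
          rownames(av) <- NULL
        } else {
          av <- cbind(v, class = character(0), lof = logical(0),
                      in_last100 = logical(0))
        }
        ann_list[[ind]] <- av
        lofv <- av[av$lof & av$transcript_id %in% covered, , drop = FALSE]
        zyg <- if (nrow(lofv)) {
          do.call(rbind, mapply(collapse_gene_alleles,
                                names(split(lofv$zygosity, lofv$transcript_id)),
                                split(lofv$zygosity, lofv$transcript_id),
                                SIMPLIFY = FALSE))
        } else data.frame(gene_id = character(), state = character())
        zyg_sp[[ind]] <- zyg
      }
      zyg_by_species[[sp]] <- rbind_all(zyg_sp)
    }
  })
  annotated <- rbind_all(ann_list)
  say("classify: %d calls annotated, %d LoF",
      if (is.null(annotated)) 0L else nrow(annotated),
      if (is.null(annotated)) 0L else sum(annotated$lof))

  # -- gene sets --------------------------------------------------------------
  all_union <- sort(unique(unlist(lapply(orf_tables[kept_species],
                                         `[[`, "transcript_id"))))
  core_union <- build_core_set(all_union, core_ids)
  hardcore_union <- build_hardcore_set(core_union, zyg_by_species)

  # -- per-individual and per-species statistics ------------------------------
  per_ind <- stage("stats", {
    rows <- list()
    for (sp in kept_species) {
      all_sp <- orf_tables[[sp]]$transcript_id
      partition <- list(all = all_sp,
                        core = intersect(all_sp, core_union),
                        hardcore = intersect(all_sp, hardcore_union))
      prof <- ind_filter$kept[ind_filter$kept$species_id == sp, ]
      for (ind in prof$individual_id) {
        st <- individual_statistics(ann_list[[ind]], covered_by_ind[[ind]],
                                    partition)
        st <- cbind(individual_id = ind, species_id = sp, st)
        rows[[length(rows) + 1L]] <- st
      }
    }
    rbind_all(rows)
  })
  per_species <- species_means(per_ind)
  summary_tab <- summary_table(per_species)

  # -- correlation ------------------------------------------------------------
  corr <- stage("correlate", {
    wide <- stats::reshape(
      per_species[per_species$variant_type == "all_lof" &
                    per_species$region == region,
                  c("species_id", "gene_set", "mean_p")],
      idvar = "species_id", timevar = "gene_set", direction = "wide")
    names(wide) <- sub("^mean_p\\.", "p_", names(wide))
    rec <- merge(inputs$traits, wide, by = "species_id")
    correlation_matrix(rec)
  })

  # -- emit -------------------------------------------------------------------
  out <- list(
    orf_table = rbind_all(mapply(function(sp, ot) {
      if (nrow(ot)) cbind(species_id = sp, ot) else NULL
    }, names(orf_tables), orf_tables, SIMPLIFY = FALSE)),
    annotated_variants = annotated,
    exclusion_log = exclusion_log,
    per_individual = per_ind,
    per_species = per_species,
    summary = summary_tab,
    correlations = corr)
  files <- c(orf_table = "orf_table.tsv",
             annotated_variants = "annotated_variants.tsv",
             exclusion_log = "exclusion_log.tsv",
             per_individual = "per_individual_stats.tsv",
             per_species = "per_species_stats.tsv",
             summary = "summary_table.tsv",
             correlations = "correlation_grid.tsv")
  paths <- character()
  for (nm in names(files)) {
    p <- file.path(out_dir, files[[nm]])
    write_tsv(out[[nm]], p)
    paths <- c(paths, p)
  }
  input_files <- list.files(input_dir, recursive = TRUE, full.names = TRUE)
  manifest <- list(mode = mode, seed = seed,
                   n_species_in = length(inputs$species_ids),
                   n_species_kept = length(kept_species),
                   n_individuals_kept = length(kept_inds),
                   n_genes_all = length(all_union),
                   n_genes_core = length(core_union),
                   n_genes_hardcore = length(hardcore_union),
                   outputs = as.vector(paths),
                   input_hashes = as.list(tools::md5sum(input_files)))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  out$manifest <- manifest
  out$manifest_path <- mpath
  out$gene_sets <- list(all = all_union, core = core_union,
                        hardcore = hardcore_union)
  invisible(out)
}
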