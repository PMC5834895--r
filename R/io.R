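# File emission and ingestion: FASTA (Biostrings), VCF v4.2 (vcfR reader,
# plain-text writer), TSV tables, and the on-disk panel layout:
#
#   dir/
#     species_traits.tsv
#     core_genes.txt
#     <species_id>/transcripts.fasta
#     <species_id>/individuals.tsv
#     <species_id>/<individual_id>.vcf
#     <species_id>/<individual_id>.coverage.tsv

fasta_header <- function(id, orf) {
  sprintf("%s gene=%s;orf=%d-%d;strand=%s", id, id,
          orf$cds_start, orf$cds_end, orf$strand)
}

write_species_fasta <- function(seqs, orfs, path) {
  dna <- Biostrings::DNAStringSet(unlist(seqs))
  names(dna) <- vapply(seq_along(seqs), function(i) {
    fasta_header(names(seqs)[i], orfs[i, ])
  }, character(1))
  Biostrings::writeXStringSet(dna, path, width = 70)
  invisible(path)
}

# Parse "id gene=..;orf=a-b;strand=±" FASTA descriptions back to an ORF table.
parse_fasta_orfs <- function(dna) {
  desc <- names(dna)
  id <- sub(" .*", "", desc)
  m <- regmatches(desc, regexec("orf=(\\d+)-(\\d+);strand=([+-])", desc))
  has <- lengths(m) == 4L
  data.frame(transcript_id = id[has],
             cds_start = as.integer(vapply(m[has], `[`, "", 2)),
             cds_end = as.integer(vapply(m[has], `[`, "", 3)),
             strand = vapply(m[has], `[`, "", 4),
             stringsAsFactors = FALSE)
}

VCF_HEADER <- c(
  "##fileformat=VCFv4.2",
  "##INFO=<ID=MQ,Number=1,Type=Integer,Description=\"Mapping quality\">",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
  "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")

write_individual_vcf <- function(variants, path, sample_id) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(VCF_HEADER, con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample_id), collapse = "\t"), con)
  if (!is.null(variants) && nrow(variants)) {
    v <- variants[order(variants$transcript_id, variants$pos), , drop = FALSE]
    gt <- ifelse(v$zygosity == "hom", "1/1", "0/1")
    writeLines(paste(v$transcript_id, v$pos, ".", v$ref, v$alt,
                     v$variant_qual, "PASS",
                     sprintf("MQ=%d", v$mapping_qual), "GT:DP",
                     sprintf("%s:%d", gt, v$depth), sep = "\t"), con)
  }
  invisible(path)
}

#' Read one individual's VCF into a variant-call table
#'
#' Expects VCF v4.2 with a QUAL column, `MQ` in INFO and `GT:DP` genotype
#' fields; multi-allelic records are decomposed into one call per alternate
#' allele. Genotypes `0/1`, `1/0`, `0|1` are heterozygous; `1/1`, `1|1`
#' homozygous; reference or missing genotypes are dropped.
#'
#' @param path VCF file path.
#' @return data frame: `transcript_id`, `pos`, `ref`, `alt`, `zygosity`,
#'   `depth`, `variant_qual`, `mapping_qual`.
#' @export
read_variant_vcf <- function(path) {
  empty <- data.frame(transcript_id = character(), pos = integer(),
                      ref = character(), alt = character(),
                      zygosity = character(), depth = integer(),
                      variant_qual = numeric(), mapping_qual = numeric(),
                      stringsAsFactors = FALSE)
  n_rec <- length(grep("^[^#]", readLines(path)))
  if (n_rec == 0L) return(empty)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")[, 1]
  dp <- suppressWarnings(as.integer(vcfR::extract.gt(vcf, element = "DP")[, 1]))
  mq <- suppressWarnings(as.integer(sub(".*MQ=(\\d+).*", "\\1", fix$INFO)))
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    alleles <- strsplit(gsub("\\|", "/", gt[i]), "/", fixed = FALSE)[[1]]
    for (a in seq_along(alts)) {
      n_alt <- sum(alleles == as.character(a))
      if (n_alt == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[a],
        zygosity = if (n_alt >= 2L) "hom" else "het",
        depth = dp[i],
        variant_qual = suppressWarnings(as.numeric(fix$QUAL[i])),
        mapping_qual = mq[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic panel (and genotypes) to a directory
#'
#' Emits one FASTA per species (designed ORF coordinates in the description
#' line, 1-based inclusive), one VCF v4.2 plus a per-gene coverage TSV per
#' individual, the species trait table, the essential ("core") gene ID list,
#' and a per-species individual QC table.
#'
#' @param panel an `lof_panel` built with sequences.
#' @param genotypes an `lof_genotypes` from [sample_individual_genotypes()].
#' @param dir output directory (created if needed).
#' @return (invisibly) the file manifest, a character vector of paths.
#' @export
write_panel <- function(panel, genotypes, dir) {
  stopifnot(inherits(panel, "lof_panel"), inherits(genotypes, "lof_genotypes"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character()
  traits_path <- file.path(dir, "species_traits.tsv")
  write_tsv(panel$species[, c("species_id", "phylum", "adult_size",
                              "body_mass", "longevity", "lifetime_fecundity",
                              "propagule_size", "genome_size", "pi_s",
                              "haplodiploid")], traits_path)
  manifest <- c(manifest, traits_path)
  core_path <- file.path(dir, "core_genes.txt")
  writeLines(panel$genes$gene_id[panel$genes$core], core_path)
  manifest <- c(manifest, core_path)
  for (sp in panel$species$species_id) {
    spdir <- file.path(dir, sp)
    dir.create(spdir, showWarnings = FALSE)
    if (length(panel$transcripts)) {
      fa <- file.path(spdir, "transcripts.fasta")
      write_species_fasta(panel$transcripts[[sp]], panel$orfs[[sp]], fa)
      manifest <- c(manifest, fa)
    }
    prof <- genotypes$profiles[genotypes$profiles$species_id == sp, ]
    ip <- file.path(spdir, "individuals.tsv")
    write_tsv(prof, ip)
    manifest <- c(manifest, ip)
    for (ind in prof$individual_id) {
      vp <- file.path(spdir, paste0(ind, ".vcf"))
      v <- genotypes$variants
      v <- if (is.null(v)) NULL else v[v$individual_id == ind, , drop = FALSE]
      write_individual_vcf(v, vp, ind)
      cp <- file.path(spdir, paste0(ind, ".coverage.tsv"))
      cov <- genotypes$coverage[genotypes$coverage$individual_id == ind,
                                c("gene_id", "min_cds_depth")]
      write_tsv(cov, cp)
      manifest <- c(manifest, vp, cp)
    }
  }
  invisible(manifest)
}

#' Read a panel directory back into typed inputs
#'
#' Validates as it reads: duplicate FASTA IDs, VCF positions beyond the
#' transcript, and unknown transcript IDs each raise a distinct, named error.
#'
#' @param dir directory written by [write_panel()] (layout in the package
#'   README).
#' @return list with `species_ids`, `transcripts` (per species, named
#'   character vectors), `orfs` (designed ORF tables parsed from headers, or
#'   `NULL`), `profiles`, `coverage`, `variants` (per-individual call tables),
#'   `traits`, `core_ids`.
#' @export
read_species_inputs <- function(dir) {
  traits <- read_species_traits(file.path(dir, "species_traits.tsv"))
  core_ids <- readLines(file.path(dir, "core_genes.txt"))
  species_ids <- traits$species_id
  transcripts <- list(); orfs <- list(); profiles <- list()
  coverage <- list(); variants <- list()
  for (sp in species_ids) {
    spdir <- file.path(dir, sp)
    fa <- file.path(spdir, "transcripts.fasta")
    if (file.exists(fa)) {
      dna <- Biostrings::readDNAStringSet(fa)
      ids <- sub(" .*", "", names(dna))
      if (anyDuplicated(ids))
        stop("duplicate transcript ID in ", fa, ": ",
             ids[duplicated(ids)][1], call. = FALSE)
      orfs[[sp]] <- parse_fasta_orfs(dna)
      seqs <- as.character(dna)
      names(seqs) <- ids
      transcripts[[sp]] <- seqs
    }
    prof <- utils::read.delim(file.path(spdir, "individuals.tsv"),
                              stringsAsFactors = FALSE)
    profiles[[sp]] <- prof
    for (ind in prof$individual_id) {
      v <- read_variant_vcf(file.path(spdir, paste0(ind, ".vcf")))
      if (nrow(v)) {
        tl <- nchar(transcripts[[sp]])
        bad <- is.na(tl[v$transcript_id])
        if (any(bad))
          stop("VCF record for unknown transcript '",
               v$transcript_id[bad][1], "' in individual ", ind,
               call. = FALSE)
        over <- v$pos + nchar(v$ref) - 1L > tl[v$transcript_id]
        if (any(over))
          stop("VCF position beyond transcript length: ",
               v$transcript_id[over][1], ":", v$pos[over][1],
               " in individual ", ind, call. = FALSE)
        v$species_id <- sp
        v$individual_id <- ind
      }
      variants[[ind]] <- v
      cov <- utils::read.delim(file.path(spdir, paste0(ind, ".coverage.tsv")),
                               stringsAsFactors = FALSE)
      cov$species_id <- sp
      cov$individual_id <- ind
      coverage[[ind]] <- cov
    }
  }
  list(species_ids = species_ids, transcripts = transcripts, orfs = orfs,
       profiles = rbind_all(profiles),
       coverage = rbind_all(coverage),
       variants = variants, traits = traits, core_ids = core_ids)
}
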