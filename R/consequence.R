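# Codon-aware variant consequence classification against a chosen ORF.
# LoF classes: stopgain, stoploss, frameshift.

GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE

translate_codon <- function(codon) {
  if (grepl("N", codon, fixed = TRUE)) return("X")
  aa <- GENETIC_CODE_TABLE[[codon]]
  if (is.null(aa)) "X" else aa
}

check_ref <- function(seq, v, id = v$transcript_id) {
  obs <- substr(seq, v$pos, v$pos + nchar(v$ref) - 1L)
  if (!identical(obs, v$ref))
    stop(sprintf(
      "reference mismatch at %s:%d (VCF says '%s', reference has '%s')",
      id, v$pos, v$ref, obs), call. = FALSE)
  invisible(TRUE)
}

# forward-sequence range of the k-th codon (1-based, reading direction)
codon_range <- function(orf, k) {
  if (orf$strand == "+") {
    st <- orf$cds_start + (k - 1L) * 3L
    c(st, st + 2L)
  } else {
    en <- orf$cds_end - (k - 1L) * 3L
    c(en - 2L, en)
  }
}

#' Classify a single-nucleotide variant against an ORF
#'
#' A substitution outside the CDS is `noncoding`. Inside, the reference and
#' alternate codons are compared on the ORF strand: a sense codon turning into
#' a stop is `stopgain`; the natural stop turning into a sense codon is
#' `stoploss`; a stop staying a stop is `synonymous` (substitutions within the
#' terminator that leave it a terminator do not truncate the protein);
#' otherwise `synonymous` or `missense` by amino-acid identity.
#'
#' @param orf one-row ORF annotation ([find_orfs()] coordinates).
#' @param seq the stored transcript sequence.
#' @param v a list or one-row data frame with `pos` (1-based), `ref`, `alt`
#'   (single bases) and optionally `transcript_id`.
#' @return one of `"noncoding"`, `"synonymous"`, `"missense"`, `"stopgain"`,
#'   `"stoploss"`.
#' @export
classify_snv <- function(orf, seq, v) {
  v <- as.list(v)
  stopifnot(nchar(v$ref) == 1L, nchar(v$alt) == 1L)
  if (v$ref == v$alt) stop("ref and alt alleles are identical")
  if (v$pos < 1L || v$pos > nchar(seq))
    stop("variant position outside the transcript")
  check_ref(seq, v)
  if (v$pos < orf$cds_start || v$pos > orf$cds_end) return("noncoding")
  off <- if (orf$strand == "+") v$pos - orf$cds_start else orf$cds_end - v$pos
  k <- off %/% 3L + 1L
  rng <- codon_range(orf, k)
  ref_codon <- substr(seq, rng[1], rng[2])
  alt_codon <- ref_codon
  substr(alt_codon, v$pos - rng[1] + 1L, v$pos - rng[1] + 1L) <- v$alt
  if (orf$strand == "-") {
    ref_codon <- revcomp(ref_codon)
    alt_codon <- revcomp(alt_codon)
  }
  ref_stop <- ref_codon %in% STOP_CODONS
  alt_stop <- alt_codon %in% STOP_CODONS
  if (ref_stop && alt_stop) return("synonymous")
  if (ref_stop && !alt_stop) return("stoploss")
  if (!ref_stop && alt_stop) return("stopgain")
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  if (ref_aa == alt_aa && ref_aa != "X") "synonymous" else "missense"
}

# positions a simple indel edits on the stored sequence: for a deletion, the
# deleted bases; for an insertion, the anchor base (the insertion lands
# between anchor and anchor + 1).
indel_edited_range <- function(v) {
  d <- nchar(v$alt) - nchar(v$ref)
  if (d < 0L) c(v$pos + 1L, v$pos + nchar(v$ref) - 1L)
  else c(v$pos, v$pos)  # insertion anchored at pos
}

#' Classify a simple insertion or deletion against an ORF
#'
#' An indel whose edited bases fall wholly outside the CDS is `noncoding`
#' (an insertion counts as coding when its anchor lies strictly inside the
#' CDS, i.e. new bases land between two coding positions). A coding indel is
#' `frameshift` when the length difference between ref and alt is not a
#' multiple of 3, otherwise `inframe_indel`.
#'
#' @inheritParams classify_snv
#' @return `"noncoding"`, `"frameshift"` or `"inframe_indel"`.
#' @export
classify_indel <- function(orf, seq, v) {
  v <- as.list(v)
  d <- nchar(v$alt) - nchar(v$ref)
  if (d == 0L) stop("not an indel: ref and alt have equal length")
  if (!(nchar(v$ref) == 1L || nchar(v$alt) == 1L))
    stop("only simple indels (one allele of length 1) are supported")
  if (v$pos < 1L || v$pos + nchar(v$ref) - 1L > nchar(seq))
    stop("variant position outside the transcript")
  check_ref(seq, v)
  coding <- if (d > 0L) {
    v$pos >= orf$cds_start && v$pos < orf$cds_end
  } else {
    rng <- indel_edited_range(v)
    rng[1] <= orf$cds_end && rng[2] >= orf$cds_start
  }
  if (!coding) return("noncoding")
  if (abs(d) %% 3L != 0L) "frameshift" else "inframe_indel"
}

#' Classify one variant (SNV or simple indel)
#' @inheritParams classify_snv
#' @return a consequence class string.
#' @export
classify_variant <- function(orf, seq, v) {
  v <- as.list(v)
  if (nchar(v$ref) == 1L && nchar(v$alt) == 1L) classify_snv(orf, seq, v)
  else classify_indel(orf, seq, v)
}

#' Classify a table of variants for one transcript
#'
#' @param orf one-row ORF annotation (or `NULL`: everything is `noncoding`).
#' @param seq the transcript sequence.
#' @param variants data frame with `pos`, `ref`, `alt`.
#' @return the input with `class`, `lof` and `in_last100` columns appended.
#' @param last_n size of the terminal CDS window used for the `in_last100`
#'   flag.
#' @export
classify_variants <- function(orf, seq, variants, last_n = 100L) {
  n <- nrow(variants)
  cls <- character(n)
  in_win <- logical(n)
  win <- if (!is.null(orf)) last_n_window(orf, last_n) else c(1L, 0L)
  for (i in seq_len(n)) {
    v <- as.list(variants[i, ])
    cls[i] <- if (is.null(orf)) "noncoding" else classify_variant(orf, seq, v)
    if (!is.null(orf)) {
      rng <- if (nchar(v$ref) == nchar(v$alt)) c(v$pos, v$pos)
             else indel_edited_range(v)
      in_win[i] <- rng[1] <= win["end"] && rng[2] >= win["start"]
    }
  }
  variants$class <- cls
  variants$lof <- is_lof(cls)
  variants$in_last100 <- in_win
  variants
}

#' Is a consequence class loss-of-function?
#'
#' Stopgain and stoploss substitutions and frameshift indels count as
#' loss-of-function; everything else does not.
#' @param x character vector of consequence classes.
#' @return logical vector.
#' @export
is_lof <- function(x) {
  x %in% c("stopgain", "stoploss", "frameshift")
}

#' Collapse a gene's LoF variants to an allele-level zygosity state
#'
#' The counting unit of the prevalence statistic is the gene allele: a gene is
#' `hom_lof` if any of its LoF variants is homozygous, else `het_lof` if any is
#' heterozygous, else `none`. Several heterozygous LoF variants collapse to a
#' single het allele (phase is unknown from unphased genotypes; this
#' undercounts compound heterozygotes conservatively).
#'
#' @param gene_id gene identifier.
#' @param zygosities character vector of `"het"` / `"hom"` for the gene's LoF
#'   variants (empty for none).
#' @return one-row data frame `gene_id`, `state`.
#' @export
collapse_gene_alleles <- function(gene_id, zygosities) {
  state <- if (any(zygosities == "hom")) "hom_lof"
           else if (any(zygosities == "het")) "het_lof"
           else "none"
  data.frame(gene_id = gene_id, state = state, stringsAsFactors = FALSE)
}

translate_nt <- function(s) {
  n <- nchar(s) %/% 3L
  if (n == 0L) return(character(0))
  starts <- seq.int(1L, by = 3L, length.out = n)
  vapply(substring(s, starts, starts + 2L), function(cod) {
    if (cod %in% STOP_CODONS) "*" else translate_codon(cod)
  }, character(1), USE.NAMES = FALSE)
}

#' Brute-force consequence oracle by re-translation
#'
#' Applies the edit to the full transcript sequence and re-derives the
#' consequence from protein-level comparison, independently of the codon
#' lookup in [classify_snv()]/[classify_indel()]. For substitutions the mutant
#' reading frame is re-translated from the original start through the end of
#' the transcript and the proteins are compared (premature stop = stopgain,
#' lost terminator = stoploss, identical = synonymous, else missense). For
#' indels the original start and stop codon coordinates are mapped through the
#' edit and the mod-3 change of the start-to-stop distance decides frameshift
#' versus in-frame.
#'
#' @inheritParams classify_snv
#' @return a consequence class string.
#' @export
translation_oracle <- function(seq, orf, v) {
  v <- as.list(v)
  if (identical(v$ref, v$alt)) stop("ref and alt alleles are identical")
  check_ref(seq, v)
  is_snv <- nchar(v$ref) == 1L && nchar(v$alt) == 1L
  mutant <- paste0(substr(seq, 1L, v$pos - 1L), v$alt,
                   substr(seq, v$pos + nchar(v$ref), nchar(seq)))

  if (is_snv) {
    if (v$pos < orf$cds_start || v$pos > orf$cds_end) return("noncoding")
    orig_cds <- orf_cds(seq, orf)
    p0 <- translate_nt(orig_cds)               # ends in "*"
    n_aa <- length(p0) - 1L
    # mutant frame from the original start, through the transcript end
    mut_read <- if (orf$strand == "+") substr(mutant, orf$cds_start, nchar(mutant))
                else revcomp(substr(mutant, 1L, orf$cds_end))
    pm_full <- translate_nt(mut_read)
    stop_at <- which(pm_full == "*")[1]
    if (is.na(stop_at)) return("stoploss")
    if (stop_at < n_aa + 1L) return("stopgain")
    if (stop_at > n_aa + 1L) return("stoploss")
    pm <- pm_full[seq_len(n_aa)]
    if (identical(pm, p0[seq_len(n_aa)])) "synonymous" else "missense"
  } else {
    d <- nchar(v$alt) - nchar(v$ref)
    ed <- indel_edited_range(v)
    coding <- if (d > 0L) v$pos >= orf$cds_start && v$pos < orf$cds_end
              else ed[1] <= orf$cds_end && ed[2] >= orf$cds_start
    if (!coding) return("noncoding")
    # map a forward coordinate through the edit (positions after a deletion
    # shift left; after an insertion anchor, right)
    map_pos <- function(p) {
      if (d < 0L) {
        if (p > ed[2]) p + d else p
      } else {
        if (p > v$pos) p + d else p
      }
    }
    if (orf$strand == "+") {
      start_m <- map_pos(orf$cds_start)
      stop_m <- map_pos(orf$cds_end)
    } else {
      start_m <- map_pos(orf$cds_end)
      stop_m <- map_pos(orf$cds_start)
    }
    span0 <- abs(orf$cds_end - orf$cds_start)
    span_m <- abs(stop_m - start_m)
    if ((span_m - span0) %% 3L != 0L) "frameshift" else "inframe_indel"
  }
}
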