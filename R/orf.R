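# ORF discovery in transcript space. Coordinates are 1-based inclusive on the
# stored (forward) sequence; the strand records the reading direction.

#' Reverse-complement a nucleotide string
#'
#' Vectorised over character input; understands A/C/G/T/N (case-sensitive,
#' upper case).
#' @param x character vector of nucleotide strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

validate_nt <- function(s, id = "sequence") {
  if (grepl("[^ACGTN]", s))
    stop(sprintf("sequence '%s' contains characters outside {A,C,G,T,N}", id),
         call. = FALSE)
  invisible(TRUE)
}

# All complete ORFs (ATG -> in-frame stop, no internal stop) in the three
# forward frames of s. Codons containing N are neither start nor stop. Nested
# ORFs (in-frame ATGs sharing a stop) are all reported.
scan_forward_frames <- function(s, min_aa) {
  L <- nchar(s)
  cs <- integer(0); ce <- integer(0); pr <- integer(0)
  for (f in 0:2) {
    n_cod <- (L - f) %/% 3L
    if (n_cod < min_aa + 1L) next
    starts <- seq.int(f + 1L, by = 3L, length.out = n_cod)
    codons <- substring(s, starts, starts + 2L)
    atg <- which(codons == "ATG")
    stops <- which(codons %in% STOP_CODONS)
    if (!length(atg) || !length(stops)) next
    nxt <- stops[findInterval(atg, stops) + 1L]
    ok <- !is.na(nxt)
    atg <- atg[ok]; nxt <- nxt[ok]
    prot <- nxt - atg
    keep <- prot >= min_aa
    if (!any(keep)) next
    cs <- c(cs, starts[atg[keep]])
    ce <- c(ce, starts[nxt[keep]] + 2L)
    pr <- c(pr, prot[keep])
  }
  list(cds_start = cs, cds_end = ce, protein_length_aa = pr)
}

#' Find open reading frames in a transcript
#'
#' Scans all six frames for complete ORFs: an ATG followed by an in-frame stop
#' codon (TAA/TAG/TGA) with no internal in-frame stop, encoding a protein of at
#' least `min_protein_aa` amino acids (stop excluded). Codons containing N are
#' treated as neither start nor stop. Minus-strand ORFs are reported in
#' coordinates of the stored forward sequence with `strand = "-"`.
#'
#' @param seq a nucleotide string over A/C/G/T/N.
#' @param id transcript identifier attached to the result.
#' @param min_protein_aa minimum protein length in amino acids (default 100,
#'   the floor the analysis applies to predicted ORFs).
#' @return a data frame with columns `transcript_id`, `cds_start`, `cds_end`
#'   (1-based inclusive, stop codon included), `strand`,
#'   `protein_length_aa`.
#' @export
find_orfs <- function(seq, id = "seq", min_protein_aa = 100L) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) >= 1L)
  validate_nt(seq, id)
  L <- nchar(seq)
  fwd <- scan_forward_frames(seq, min_protein_aa)
  rev <- scan_forward_frames(revcomp(seq), min_protein_aa)
  data.frame(
    transcript_id = if (length(fwd$cds_start) + length(rev$cds_start))
      id else character(0),
    cds_start = as.integer(c(fwd$cds_start, L - rev$cds_end + 1L)),
    cds_end = as.integer(c(fwd$cds_end, L - rev$cds_start + 1L)),
    strand = c(rep("+", length(fwd$cds_start)),
               rep("-", length(rev$cds_start))),
    protein_length_aa = as.integer(c(fwd$protein_length_aa,
                                     rev$protein_length_aa)),
    stringsAsFactors = FALSE)
}

#' Select the single ORF used for a transcript
#'
#' The longest ORF wins (the rule applied when a contig yields several
#' predictions); ties are broken in favour of the plus strand, then the
#' smallest `cds_start`.
#'
#' @param orfs a data frame as returned by [find_orfs()] (one transcript).
#' @return a one-row data frame, or `NULL` for empty input.
#' @export
select_longest_orf <- function(orfs) {
  if (is.null(orfs) || nrow(orfs) == 0L) return(NULL)
  if (length(unique(orfs$transcript_id)) > 1L)
    stop("select_longest_orf expects ORFs of a single transcript")
  o <- order(-orfs$protein_length_aa, orfs$strand != "+", orfs$cds_start)
  orfs[o[1L], , drop = FALSE]
}

#' Terminal window of a CDS
#'
#' The final `n` nucleotides of the coding sequence in reading direction (stop
#' codon included), clamped to the CDS length — the positional proxy for the
#' last exon, where nonsense-mediated decay does not act.
#'
#' @param orf a one-row ORF annotation.
#' @param n window size in nucleotides (default 100).
#' @return integer vector `c(start, end)`, 1-based inclusive on the stored
#'   sequence; `start > end` encodes the empty window (`n = 0`).
#' @export
last_n_window <- function(orf, n = 100L) {
  if (n < 0) stop("window size must be non-negative")
  w <- orf$cds_end - orf$cds_start + 1L
  m <- min(as.integer(n), w)
  if (orf$strand == "+") {
    c(start = orf$cds_end - m + 1L, end = orf$cds_end)
  } else {
    c(start = orf$cds_start, end = orf$cds_start + m - 1L)
  }
}

#' Annotate a set of transcripts with their chosen ORFs
#'
#' Runs [find_orfs()] + [select_longest_orf()] over a named character vector of
#' sequences; transcripts without a qualifying ORF are dropped.
#'
#' @param seqs named character vector (or `Biostrings::DNAStringSet`).
#' @param min_protein_aa minimum protein length.
#' @return ORF table: one row per transcript with a qualifying ORF.
#' @export
annotate_orfs <- function(seqs, min_protein_aa = 100L) {
  if (methods::is(seqs, "DNAStringSet")) {
    nm <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- nm
  }
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("transcript IDs must be present and unique")
  n <- length(seqs)
  cs <- integer(n); ce <- integer(n); pr <- integer(n)
  strand <- character(n); hit <- logical(n)
  for (i in seq_len(n)) {
    s <- seqs[[i]]
    validate_nt(s, names(seqs)[i])
    L <- nchar(s)
    fwd <- scan_forward_frames(s, min_protein_aa)
    rev <- scan_forward_frames(revcomp(s), min_protein_aa)
    a <- c(fwd$cds_start, L - rev$cds_end + 1L)
    if (!length(a)) next
    b <- c(fwd$cds_end, L - rev$cds_start + 1L)
    p <- c(fwd$protein_length_aa, rev$protein_length_aa)
    st <- rep(c("+", "-"), c(length(fwd$cds_start), length(rev$cds_start)))
    best <- order(-p, st != "+", a)[1L]
    hit[i] <- TRUE
    cs[i] <- a[best]; ce[i] <- b[best]; pr[i] <- p[best]
    strand[i] <- st[best]
  }
  data.frame(transcript_id = names(seqs)[hit], cds_start = cs[hit],
             cds_end = ce[hit], strand = strand[hit],
             protein_length_aa = pr[hit], stringsAsFactors = FALSE)
}

#' Extract the CDS of an annotated ORF on its reading strand
#' @param seq stored forward sequence.
#' @param orf one-row ORF annotation.
#' @return nucleotide string beginning with ATG and ending with a stop codon.
#' @export
orf_cds <- function(seq, orf) {
  cds <- substr(seq, orf$cds_start, orf$cds_end)
  if (orf$strand == "-") revcomp(cds) else cds
}

#' @rdname write_orf_table
#' @export
read_orf_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read/write an ORF table TSV
#'
#' Columns: transcript_id, cds_start, cds_end (1-based inclusive), strand,
#' protein_length_aa.
#' @param orfs ORF table.
#' @param path file path.
#' @export
write_orf_table <- function(orfs, path) {
  utils::write.table(orfs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
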