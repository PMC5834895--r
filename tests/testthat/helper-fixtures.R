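# Shared fixtures and independent brute-force oracles.

BASES <- c("A", "C", "G", "T")
STOPS <- c("TAA", "TAG", "TGA")
SENSE <- setdiff(as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0)),
                 STOPS)
GC <- Biostrings::GENETIC_CODE

rc <- function(s) {
  vapply(strsplit(chartr("ACGTN", "TGCAN", s), ""),
         function(x) paste(rev(x), collapse = ""), character(1))
}

# A transcript with one designed ORF: UTR5 + ATG + (n_codons - 2) sense
# codons + stop + UTR3, optionally stored reverse-complemented.
# `no_atg` keeps internal codons free of ATG so the designed ORF is unique.
make_toy_transcript <- function(n_codons = 110, utr5 = 12, utr3 = 9,
                                strand = "+", no_atg = FALSE,
                                stop_codon = "TAA") {
  pool <- if (no_atg) setdiff(SENSE, "ATG") else SENSE
  cds <- paste0("ATG",
                paste(sample(pool, n_codons - 2, replace = TRUE),
                      collapse = ""),
                stop_codon)
  seq <- paste0(paste(sample(BASES, utr5, replace = TRUE), collapse = ""),
                cds,
                paste(sample(BASES, utr3, replace = TRUE), collapse = ""))
  L <- nchar(seq)
  orf <- data.frame(transcript_id = "t1", cds_start = utr5 + 1L,
                    cds_end = utr5 + 3L * n_codons, strand = "+",
                    protein_length_aa = n_codons - 1L,
                    stringsAsFactors = FALSE)
  if (strand == "-") {
    seq <- rc(seq)
    new_start <- L - orf$cds_end + 1L
    orf$cds_end <- L - orf$cds_start + 1L
    orf$cds_start <- new_start
    orf$strand <- "-"
  }
  list(seq = seq, orf = orf)
}

# Naive quadratic ORF oracle: for every position and both strands, if the
# codon is ATG, walk forward codon by codon to the first stop; report the ORF
# if the protein is long enough. Deliberately simple and slow.
brute_force_orfs <- function(s, min_aa = 100) {
  out <- list()
  for (strand in c("+", "-")) {
    w <- if (strand == "+") s else rc(s)
    L <- nchar(w)
    for (i in seq_len(L - 2)) {
      if (substr(w, i, i + 2) != "ATG") next
      j <- i
      found <- FALSE
      while (j + 2 <= L) {
        cod <- substr(w, j, j + 2)
        if (cod %in% STOPS) { found <- TRUE; break }
        j <- j + 3
      }
      if (!found) next
      prot <- (j - i) / 3
      if (prot < min_aa) next
      a <- i; b <- j + 2
      if (strand == "-") { tmp <- a; a <- L - b + 1; b <- L - tmp + 1 }
      out[[length(out) + 1L]] <- data.frame(cds_start = a, cds_end = b,
                                            strand = strand,
                                            protein_length_aa = prot)
    }
  }
  if (!length(out)) return(data.frame(cds_start = integer(),
                                      cds_end = integer(),
                                      strand = character(),
                                      protein_length_aa = integer()))
  d <- do.call(rbind, out)
  d[order(d$strand, d$cds_start, d$cds_end), ]
}

# Rank-difference Spearman for tie-free vectors: 1 - 6*sum(d^2)/(n(n^2-1)).
spearman_rank_formula <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Small config for fast end-to-end runs; floors lowered to match its size.
tiny_config <- function(...) {
  simulation_config(n_species = 4, genes_per_species = 50,
                    core_fraction = 0.2, mu_lof_per_gene = 1e-3,
                    individuals_per_species = 2, seed = 11, ...)
}
tiny_floors <- list(min_orfs = 0, min_core = 0)
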