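make_snv <- function(seq, pos, alt) {
  list(transcript_id = "t1", pos = pos, ref = substr(seq, pos, pos), alt = alt)
}

test_that("canonical substitutions classify by the genetic code", {
  set.seed(21)
  tt <- make_toy_transcript(n_codons = 110, utr5 = 10, utr3 = 10)
  s <- tt$seq; orf <- tt$orf
  # plant TGG at codon 5 (positions 23..25 on + strand with utr5 = 10)
  substr(s, 23, 25) <- "TGG"
  expect_equal(classify_snv(orf, s, make_snv(s, 25, "A")), "stopgain")  # TGG->TGA
  # terminal stop -> sense codon
  substr(s, orf$cds_end - 2, orf$cds_end) <- "TAA"
  expect_equal(classify_snv(orf, s, make_snv(s, orf$cds_end - 2, "C")),
               "stoploss")                                              # TAA->CAA
  # wobble position of Ala codon GCT
  substr(s, 26, 28) <- "GCT"
  expect_equal(classify_snv(orf, s, make_snv(s, 28, "C")), "synonymous")
  # GCT -> CCT is Ala -> Pro
  expect_equal(classify_snv(orf, s, make_snv(s, 26, "C")), "missense")
  # outside the CDS
  expect_equal(classify_snv(orf, s, make_snv(s, 3, setdiff(BASES, substr(s, 3, 3))[1])),
               "noncoding")
})

test_that("a stop-to-stop substitution in the terminator is synonymous", {
  set.seed(22)
  tt <- make_toy_transcript(n_codons = 105, utr5 = 6, utr3 = 6,
                            stop_codon = "TAA")
  s <- tt$seq; orf <- tt$orf
  expect_equal(classify_snv(orf, s, make_snv(s, orf$cds_end, "G")),
               "synonymous")  # TAA -> TAG
})

test_that("indel classes follow the mod-3 rule with CDS overlap", {
  set.seed(23)
  tt <- make_toy_transcript(n_codons = 104, utr5 = 8, utr3 = 8)
  s <- tt$seq; orf <- tt$orf
  p <- orf$cds_start + 30
  del1 <- list(pos = p, ref = substr(s, p, p + 1), alt = substr(s, p, p))
  expect_equal(classify_indel(orf, s, del1), "frameshift")
  del3 <- list(pos = p, ref = substr(s, p, p + 3), alt = substr(s, p, p))
  expect_equal(classify_indel(orf, s, del3), "inframe_indel")
  # 2-bp insertion anchored at the first CDS base lands inside the CDS
  ins2 <- list(pos = orf$cds_start, ref = substr(s, orf$cds_start, orf$cds_start),
               alt = paste0(substr(s, orf$cds_start, orf$cds_start), "GT"))
  expect_equal(classify_indel(orf, s, ins2), "frameshift")
  expect_equal(translation_oracle(s, orf, ins2), "frameshift")
  # deletion wholly in the 3' UTR
  q <- orf$cds_end + 2
  del_utr <- list(pos = q, ref = substr(s, q, q + 1), alt = substr(s, q, q))
  expect_equal(classify_indel(orf, s, del_utr), "noncoding")
})

test_that("reference mismatches raise a named data-integrity error", {
  set.seed(24)
  tt <- make_toy_transcript()
  wrong_ref <- setdiff(BASES, substr(tt$seq, 30, 30))
  v <- list(transcript_id = "t1", pos = 30, ref = wrong_ref[1],
            alt = wrong_ref[2])
  expect_error(classify_snv(tt$orf, tt$seq, v), "reference mismatch.*t1:30")
})

test_that("LoF membership is exactly stopgain, stoploss, frameshift", {
  expect_equal(is_lof(c("stopgain", "stoploss", "frameshift", "missense",
                        "synonymous", "inframe_indel", "noncoding")),
               c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("gene-allele collapsing prefers hom over het over none", {
  expect_equal(collapse_gene_alleles("g1", character(0))$state, "none")
  expect_equal(collapse_gene_alleles("g1", "het")$state, "het_lof")
  expect_equal(collapse_gene_alleles("g1", c("het", "het", "hom"))$state,
               "hom_lof")
})

test_that("classifier and re-translation oracle agree on random SNVs", {
  set.seed(25)
  for (strand in c("+", "-")) {
    tt <- make_toy_transcript(n_codons = 105, utr5 = 15, utr3 = 12,
                              strand = strand)
    s <- tt$seq; orf <- tt$orf
    for (i in 1:300) {
      pos <- sample.int(nchar(s), 1)
      ref <- substr(s, pos, pos)
      alt <- sample(setdiff(BASES, ref), 1)
      v <- list(transcript_id = "t1", pos = pos, ref = ref, alt = alt)
      expect_equal(classify_snv(orf, s, v), translation_oracle(s, orf, v),
                   info = sprintf("strand %s pos %d %s>%s", strand, pos, ref, alt))
    }
  }
})

test_that("classifier and oracle agree on random 1-6 bp indels inside the CDS", {
  set.seed(26)
  for (strand in c("+", "-")) {
    tt <- make_toy_transcript(n_codons = 105, utr5 = 15, utr3 = 12,
                              strand = strand)
    s <- tt$seq; orf <- tt$orf
    for (i in 1:200) {
      len <- sample(1:6, 1)
      if (runif(1) < 0.5) {  # deletion, clear of the start and stop codons
        pos <- sample((orf$cds_start + 3):(orf$cds_end - 3 - len), 1)
        v <- list(transcript_id = "t1", pos = pos,
                  ref = substr(s, pos, pos + len), alt = substr(s, pos, pos))
      } else {               # insertion
        pos <- sample((orf$cds_start + 3):(orf$cds_end - 4), 1)
        ref <- substr(s, pos, pos)
        v <- list(transcript_id = "t1", pos = pos, ref = ref,
                  alt = paste0(ref, paste(sample(BASES, len, replace = TRUE),
                                          collapse = "")))
      }
      expect_equal(classify_indel(orf, s, v), translation_oracle(s, orf, v))
    }
  }
})

test_that("minus-strand classification equals mirrored plus-strand classification", {
  set.seed(27)
  tt <- make_toy_transcript(n_codons = 102, utr5 = 10, utr3 = 10, strand = "+")
  s <- tt$seq; orf <- tt$orf
  s_rc <- rc(s)
  L <- nchar(s)
  orf_rc <- orf
  orf_rc$cds_start <- L - orf$cds_end + 1L
  orf_rc$cds_end <- L - orf$cds_start + 1L
  orf_rc$strand <- "-"
  for (i in 1:100) {
    pos <- sample.int(L, 1)
    ref <- substr(s, pos, pos)
    alt <- sample(setdiff(BASES, ref), 1)
    v <- list(transcript_id = "t1", pos = pos, ref = ref, alt = alt)
    v_rc <- list(transcript_id = "t1", pos = L - pos + 1L,
                 ref = rc(ref), alt = rc(alt))
    expect_equal(classify_snv(orf, s, v), classify_snv(orf_rc, s_rc, v_rc))
  }
})

test_that("identity edits are rejected", {
  tt <- make_toy_transcript()
  v <- list(transcript_id = "t1", pos = 5, ref = substr(tt$seq, 5, 5),
            alt = substr(tt$seq, 5, 5))
  expect_error(classify_snv(tt$orf, tt$seq, v), "identical")
  expect_error(translation_oracle(tt$seq, tt$orf, v), "identical")
})

test_that("classify_variants flags LoF calls in the terminal window", {
  set.seed(28)
  tt <- make_toy_transcript(n_codons = 110, utr5 = 5, utr3 = 5)
  s <- tt$seq; orf <- tt$orf
  win <- last_n_window(orf, 100)
  inside <- win["start"] + 10
  outside <- orf$cds_start + 3
  vs <- data.frame(pos = c(inside, outside),
                   ref = c(substr(s, inside, inside + 1),
                           substr(s, outside, outside + 1)),
                   alt = c(substr(s, inside, inside),
                           substr(s, outside, outside)),
                   stringsAsFactors = FALSE)
  out <- classify_variants(orf, s, vs)
  expect_equal(out$class, c("frameshift", "frameshift"))
  expect_equal(out$in_last100, c(TRUE, FALSE))
})
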