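make_calls <- function(depth, vq = 30, mq = 30) {
  data.frame(transcript_id = sprintf("t%d", seq_along(depth)), pos = 1,
             ref = "A", alt = "T", zygosity = "het", depth = depth,
             variant_qual = vq, mapping_qual = mq, stringsAsFactors = FALSE)
}

test_that("site filters are strict: depth must exceed 5, qualities exceed 20", {
  t <- site_thresholds()
  expect_equal(nrow(filter_variant_calls(make_calls(5), t)), 0)   # boundary out
  expect_equal(nrow(filter_variant_calls(make_calls(6, 21, 30), t)), 1)
  expect_equal(nrow(filter_variant_calls(make_calls(10, 20, 30), t)), 0)
  expect_equal(nrow(filter_variant_calls(make_calls(10, 30, 20), t)), 0)
  # depths 1..10 at quality 30: exactly 5 survive (6,7,8,9,10)
  expect_equal(nrow(filter_variant_calls(make_calls(1:10), t)), 5)
})

test_that("the strict20x preset keeps only at-least-20x sites", {
  t20 <- site_thresholds(preset = "strict20x")
  expect_equal(nrow(filter_variant_calls(make_calls(19), t20)), 0)
  expect_equal(nrow(filter_variant_calls(make_calls(20), t20)), 1)
})

test_that("fully sequenced means every CDS position above the depth floor", {
  orfs <- data.frame(transcript_id = c("a", "b"), cds_start = c(4, 1),
                     cds_end = c(9, 6), strand = "+")
  tracks <- list(a = c(9, 9, 9, 9, 9, 0, 9, 9, 9, 9),  # one zero inside CDS
                 b = rep(10, 8))
  expect_equal(fully_sequenced_orfs(tracks, orfs), "b")
  tracks$a[6] <- 10
  expect_equal(fully_sequenced_orfs(tracks, orfs), c("a", "b"))
})

test_that("individual exclusion uses 'below excludes, boundary kept' semantics", {
  prof <- data.frame(
    individual_id = sprintf("i%d", 1:6), species_id = "sp",
    mean_coverage = c(10.0, 9.9, 30, 30, 30, 12),
    alignment_rate = c(0.80, 0.9, 0.79, 0.9, 0.9, 0.85),
    n_covered_orfs = c(5000, 6000, 6000, 4999, 6000, 5500),
    n_covered_core = c(100, 200, 200, 200, 99, 150),
    stringsAsFactors = FALSE)
  res <- filter_individuals(prof)
  expect_setequal(res$kept$individual_id, c("i1", "i6"))
  expect_equal(nrow(res$kept) + nrow(res$log), nrow(prof))  # partition
  expect_equal(res$log$failed_criterion[res$log$id == "i2"], "coverage")
  expect_equal(res$log$failed_criterion[res$log$id == "i3"], "alignment_rate")
  expect_equal(res$log$failed_criterion[res$log$id == "i4"], "covered_orfs")
  expect_equal(res$log$failed_criterion[res$log$id == "i5"], "covered_core")
})

test_that("species exclusion applies floors and the haplodiploidy flag", {
  st <- data.frame(
    species_id = sprintf("s%d", 1:5),
    alignment_rate = c(0.70, 0.69, 0.9, 0.9, 0.9),
    n_orfs = c(5000, 6000, 4999, 6000, 6000),
    n_core = c(100, 200, 200, 99, 200),
    haplodiploid = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  res <- filter_species(st)
  expect_equal(res$kept$species_id, "s1")  # boundary values kept
  expect_equal(res$log$failed_criterion[res$log$id == "s5"], "haplodiploid")
})

test_that("raising any threshold never enlarges the kept set", {
  set.seed(31)
  calls <- make_calls(sample(0:40, 200, replace = TRUE),
                      vq = sample(0:60, 200, replace = TRUE),
                      mq = sample(0:60, 200, replace = TRUE))
  base_kept <- nrow(filter_variant_calls(calls, site_thresholds()))
  for (i in 1:20) {
    t2 <- site_thresholds(min_depth_exclusive = 5 + sample(0:20, 1),
                          min_qual_exclusive = 20 + sample(0:20, 1),
                          min_mapq_exclusive = 20 + sample(0:20, 1))
    expect_lte(nrow(filter_variant_calls(calls, t2)), base_kept)
  }
  prof <- data.frame(individual_id = sprintf("i%d", 1:50), species_id = "sp",
                     mean_coverage = runif(50, 5, 40),
                     alignment_rate = runif(50, 0.5, 1),
                     n_covered_orfs = sample(3000:8000, 50),
                     n_covered_core = sample(50:300, 50))
  k1 <- filter_individuals(prof)$kept$individual_id
  k2 <- filter_individuals(prof, min_coverage = 15,
                           min_alignment_rate = 0.9)$kept$individual_id
  expect_true(all(k2 %in% k1))
})

test_that("core set is the intersection with the essential catalogue", {
  all_genes <- sprintf("g%03d", 1:1000)
  ess <- sprintf("g%03d", sample(1:1000, 100))
  core <- build_core_set(all_genes, ess)
  expect_equal(length(core), 100)
  expect_setequal(core, all_genes[all_genes %in% ess])  # brute-force scan
  expect_warning(empty <- build_core_set(all_genes, character(0)), "empty")
  expect_equal(length(empty), 0)
  expect_equal(length(build_core_set(all_genes, c("x1", "x2"))), 0)
})

test_that("one homozygote anywhere removes a gene from the hard-core set", {
  core <- sprintf("g%d", 1:5)
  zyg <- list(
    spA = data.frame(gene_id = c("g2", "g1"), state = c("hom_lof", "het_lof")),
    spB = data.frame(gene_id = "g4", state = "hom_lof"))
  expect_setequal(build_hardcore_set(core, zyg), c("g1", "g3", "g5"))
  no_hom <- list(spA = data.frame(gene_id = "g1", state = "het_lof"))
  expect_setequal(build_hardcore_set(core, no_hom), core)
  expect_setequal(build_hardcore_set(core, list()), core)
})
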