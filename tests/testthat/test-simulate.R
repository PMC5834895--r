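test_that("equilibrium frequencies follow q = u/s and respect coupling", {
  cfg <- simulation_config(n_species = 5, genes_per_species = 20,
                           mu_lof_per_gene = 1e-5, sel_coeff = 0.01,
                           coupling_beta = 0, seed = 51)
  panel <- build_species_panel(cfg, build_sequences = FALSE)
  expect_true(all(panel$q == 1e-3))  # beta = 0: identical q everywhere
  cfg1 <- simulation_config(n_species = 6, genes_per_species = 10,
                            mu_lof_per_gene = 1e-5, sel_coeff = 0.01,
                            fecundity_range = c(10, 1000),
                            coupling_beta = 1, seed = 52)
  p1 <- build_species_panel(cfg1, build_sequences = FALSE)
  f_ref <- sqrt(10 * 1000)
  expect_equal(f_ref, 100)
  want <- 1e-5 / (0.01 * p1$species$lifetime_fecundity / f_ref)
  expect_equal(unname(p1$q[1, ]), want, tolerance = 1e-12)
  # hand-evaluated endpoints: F = 10 -> q = 1e-2, F = 1000 -> q = 1e-4
  expect_equal(1e-5 / (0.01 * (10 / 100)^1), 1e-2)
  expect_equal(1e-5 / (0.01 * (1000 / 100)^1), 1e-4)
})

test_that("an empty panel is valid and empty", {
  cfg <- simulation_config(n_species = 0, seed = 1)
  panel <- build_species_panel(cfg)
  expect_equal(nrow(panel$species), 0)
  expect_equal(length(panel$transcripts), 0)
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(gene_length_nt = 300), "303")
  expect_error(simulation_config(gene_length_nt = 304), "divisible")
  expect_error(simulation_config(sel_coeff = 0, mu_lof_per_gene = 1e-5),
               "undefined")
  expect_error(simulation_config(core_fraction = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(coverage_dropout = -0.1), "\\[0, 1\\]")
  # u = 0 with s = 0 is fine (no mutation, no equilibrium needed)
  expect_s3_class(simulation_config(mu_lof_per_gene = 0, sel_coeff = 1),
                  "lof_sim_config")
})

test_that("core flag count equals round(core_fraction * genes)", {
  for (frac in c(0, 0.13, 0.5, 1)) {
    cfg <- simulation_config(n_species = 1, genes_per_species = 37,
                             core_fraction = frac, seed = 53)
    panel <- build_species_panel(cfg, build_sequences = FALSE)
    expect_equal(sum(panel$genes$core), round(frac * 37))
  }
})

test_that("expected LoF proportion is the mean allele frequency of the set", {
  cfg <- simulation_config(n_species = 3, genes_per_species = 10,
                           mu_lof_per_gene = 1e-5, sel_coeff = 0.01,
                           core_fraction = 0.5, seed = 54)
  panel <- build_species_panel(cfg, build_sequences = FALSE)
  expect_equal(expected_lof_proportion(panel, "all"), 1e-3)
  # half the genes q = 0, half q = 0.01 -> mean 0.005
  panel$q[1:5, ] <- 0
  panel$q[6:10, ] <- 0.01
  expect_equal(expected_lof_proportion(panel, "all"), 0.005)
  expect_error(expected_lof_proportion(panel, "not-a-set"), "unknown")
  expect_error(expected_lof_proportion(panel, c("g00001", "zzz")), "unknown")
})

test_that("genotypes follow Hardy-Weinberg expectations", {
  cfg <- simulation_config(n_species = 1, genes_per_species = 10000,
                           mu_lof_per_gene = 5e-3, sel_coeff = 0.01,  # q = 0.5
                           individuals_per_species = 1,
                           coverage_dropout = 0, seed = 55)
  panel <- build_species_panel(cfg, build_sequences = FALSE)
  geno <- sample_individual_genotypes(panel)
  n_hom <- sum(geno$genotypes$zygosity == "hom")
  n_het <- sum(geno$genotypes$zygosity == "het")
  sd_hom <- sqrt(10000 * 0.25 * 0.75)
  expect_lt(abs(n_hom - 2500), 3 * sd_hom)
  sd_het <- sqrt(10000 * 0.5 * 0.5)
  expect_lt(abs(n_het - 5000), 3 * sd_het)
})

test_that("zero mutation rate yields zero variants", {
  cfg <- simulation_config(n_species = 2, genes_per_species = 30,
                           mu_lof_per_gene = 0, sel_coeff = 0.01,
                           background_var_rate = 0, seed = 56)
  panel <- build_species_panel(cfg)
  geno <- sample_individual_genotypes(panel)
  expect_equal(nrow(geno$genotypes), 0)
  expect_null(geno$variants)
})

test_that("the same seed reproduces the panel byte for byte", {
  run <- function() {
    cfg <- simulation_config(n_species = 2, genes_per_species = 30,
                             mu_lof_per_gene = 2e-3, seed = 7)
    panel <- build_species_panel(cfg)
    geno <- sample_individual_genotypes(panel)
    d <- tempfile()
    write_panel(panel, geno, d)
    rel <- list.files(d, recursive = TRUE)
    hashes <- unname(tools::md5sum(file.path(d, rel)))
    unlink(d, recursive = TRUE)
    list(rel = rel, hashes = hashes)
  }
  expect_identical(run(), run())
})

test_that("synthesised LoF variants classify as their requested type", {
  cfg <- simulation_config(n_species = 2, genes_per_species = 80,
                           mu_lof_per_gene = 2e-3, sel_coeff = 0.01,  # q = 0.2
                           background_var_rate = 0, seed = 57)
  panel <- build_species_panel(cfg)
  geno <- sample_individual_genotypes(panel)
  expect_gt(nrow(geno$variants), 10)
  for (i in seq_len(nrow(geno$variants))) {
    v <- geno$variants[i, ]
    sp <- v$species_id
    orf <- panel$orfs[[sp]][panel$orfs[[sp]]$transcript_id == v$transcript_id, ]
    cls <- classify_variant(orf, panel$transcripts[[sp]][[v$transcript_id]], v)
    expect_true(is_lof(cls), info = paste(v$transcript_id, v$pos, cls))
  }
})

test_that("designed transcripts carry exactly the designed ORF", {
  cfg <- simulation_config(n_species = 1, genes_per_species = 40, seed = 58)
  panel <- build_species_panel(cfg)
  orfs <- panel$orfs[[1]]
  seqs <- panel$transcripts[[1]]
  for (i in seq_len(nrow(orfs))) {
    cds <- orf_cds(seqs[[orfs$transcript_id[i]]], orfs[i, ])
    expect_equal(substr(cds, 1, 3), "ATG")
    expect_true(substr(cds, nchar(cds) - 2, nchar(cds)) %in% STOPS)
    expect_equal(nchar(cds), cfg$gene_length_nt)
  }
})

test_that("coverage dropout marks the expected fraction as not fully sequenced", {
  cfg <- simulation_config(n_species = 1, genes_per_species = 5000,
                           individuals_per_species = 1,
                           coverage_dropout = 0.3, seed = 59)
  panel <- build_species_panel(cfg, build_sequences = FALSE)
  geno <- sample_individual_genotypes(panel)
  frac_in <- mean(geno$coverage$min_cds_depth > 5)
  expect_lt(abs(frac_in - 0.7), 3 * sqrt(0.3 * 0.7 / 5000))
})

test_that("calibration preset hits the configured grand mean in expectation", {
  cfg <- calibration_config(n_species = 35, genes_per_species = 3000,
                            seed = 60)
  panel <- build_species_panel(cfg, build_sequences = FALSE)
  m <- expected_lof_proportion(panel, "all")
  # mixture + species-scale noise: generous 3-sigma band around 0.0221
  expect_lt(abs(m - 0.0221), 0.006)
  m_core <- expected_lof_proportion(panel, "core")
  expect_lt(abs(m_core - 0.0108), 0.009)
  constrained <- panel$genes$gene_id[panel$genes$core & !panel$genes$relaxed]
  m_hc <- expected_lof_proportion(panel, constrained)
  expect_lt(abs(m_hc - 0.0022), 0.001)
})

test_that("fecundity spans the configured range on the log scale", {
  cfg <- simulation_config(n_species = 200, genes_per_species = 1,
                           fecundity_range = c(2, 1e6), seed = 61)
  panel <- build_species_panel(cfg, build_sequences = FALSE)
  f <- panel$species$lifetime_fecundity
  expect_true(all(f >= 2 & f <= 1e6))
  lf <- log(f)
  expect_lt(abs(mean(lf) - mean(log(c(2, 1e6)))), 3 * sd(lf) / sqrt(200))
})
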