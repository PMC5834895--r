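# Synthetic multi-species panels under deterministic mutation-selection balance.
# Allele frequencies follow q = u/s (heterozygous selection); genotypes are
# drawn under Hardy-Weinberg. No drift is simulated.

#' Simulation configuration
#'
#' Parameters of the synthetic multi-species panel generator. Defaults describe
#' the panel the package's own analyses run on: 35 diploid metazoan species,
#' 5000 single-isoform genes each, two sequenced individuals per species, and a
#' per-gene LoF mutation rate / selection coefficient pair whose deterministic
#' mutation-selection equilibrium is q = u/s = 2.2e-3.
#'
#' @param n_species number of species in the panel.
#' @param genes_per_species number of genes (one transcript each) per species.
#' @param core_fraction fraction of genes flagged as essential ("core").
#' @param gene_length_nt coding length in nucleotides including the stop codon;
#'   must be divisible by 3 and at least 303 (100 aa + stop).
#' @param mu_lof_per_gene per-generation LoF mutation rate u per gene.
#' @param sel_coeff heterozygous selection coefficient s against a LoF allele.
#' @param fecundity_range length-2 numeric, min and max lifetime fecundity;
#'   species fecundities are sampled log-uniformly on this interval.
#' @param coupling_beta exponent linking selection to fecundity:
#'   \eqn{s_i = s (F_i/F_{ref})^\beta} with \eqn{F_{ref}} the geometric mean of
#'   `fecundity_range`. `beta = 0` gives identical q across species.
#' @param individuals_per_species diploid individuals sampled per species.
#' @param coverage_dropout fraction of ORFs not fully sequenced per individual.
#' @param depth_mean mean per-site read depth.
#' @param type_weights named numeric weights for drawing the variant type of a
#'   LoF carrier among `stopgain`, `frameshift`, `stoploss`.
#' @param background_var_rate per-gene per-individual probability of an extra
#'   non-LoF-targeted random SNV (exercises the classifier; most such variants
#'   are synonymous or missense).
#' @param s_jitter_sd sdlog of an optional lognormal per-gene multiplier on s
#'   (mean 1); 0 keeps s constant across genes.
#' @param utr_range length-2 integer, min/max UTR length flanking the CDS.
#' @param minus_strand_fraction fraction of transcripts stored in reverse
#'   orientation (designed ORF on the minus strand).
#' @param q_model `"equilibrium"` (q = u/s) or `"calibration"` (mixture preset,
#'   see [calibration_config()]).
#' @param seed integer root seed; all per-species and per-individual streams
#'   are derived from it deterministically.
#' @return an object of class `lof_sim_config` (a validated list).
#' @export
simulation_config <- function(n_species = 35L,
                              genes_per_species = 5000L,
                              core_fraction = 0.1,
                              gene_length_nt = 501L,
                              mu_lof_per_gene = 2.2e-5,
                              sel_coeff = 0.01,
                              fecundity_range = c(2, 1e6),
                              coupling_beta = 0,
                              individuals_per_species = 2L,
                              coverage_dropout = 0.2,
                              depth_mean = 30,
                              type_weights = c(stopgain = 0.20,
                                               frameshift = 0.75,
                                               stoploss = 0.05),
                              background_var_rate = 0.01,
                              s_jitter_sd = 0,
                              utr_range = c(20L, 60L),
                              minus_strand_fraction = 0.3,
                              q_model = c("equilibrium", "calibration"),
                              seed = 1L) {
  q_model <- match.arg(q_model)
  cfg <- list(n_species = as.integer(n_species),
              genes_per_species = as.integer(genes_per_species),
              core_fraction = core_fraction,
              gene_length_nt = as.integer(gene_length_nt),
              mu_lof_per_gene = mu_lof_per_gene,
              sel_coeff = sel_coeff,
              fecundity_range = as.numeric(fecundity_range),
              coupling_beta = coupling_beta,
              individuals_per_species = as.integer(individuals_per_species),
              coverage_dropout = coverage_dropout,
              depth_mean = depth_mean,
              type_weights = type_weights,
              background_var_rate = background_var_rate,
              s_jitter_sd = s_jitter_sd,
              utr_range = as.integer(utr_range),
              minus_strand_fraction = minus_strand_fraction,
              q_model = q_model,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "lof_sim_config"
  cfg
}

#' Calibration preset configuration
#'
#' A [simulation_config()] whose per-gene allele frequencies are drawn from a
#' two-component mixture calibrated so that, in expectation, the mean q is
#' 0.0022 over hard-core genes, 0.0108 over core genes and 0.0221 over all
#' genes: most genes are "constrained" (q = 0.0022) and a small "relaxed"
#' fraction has q ~ Uniform(0.2, 0.8). Relaxed genes almost surely reveal a
#' homozygous LoF somewhere in the panel and are therefore purged from the
#' hard-core set downstream. A per-species lognormal scale factor (sdlog
#' `species_sdlog`) spreads species means over roughly an order of magnitude.
#'
#' @param species_sdlog sdlog of the per-species multiplicative factor on q.
#' @param ... overrides passed to [simulation_config()].
#' @return an `lof_sim_config` with `q_model = "calibration"`.
#' @export
calibration_config <- function(species_sdlog = 0.6, ...) {
  cfg <- simulation_config(q_model = "calibration", coupling_beta = 0, ...)
  cfg$calibration <- list(
    q_constrained = 0.0022,
    q_relaxed_range = c(0.2, 0.8),
    # solve pi*mean(relaxed) + (1-pi)*q_constrained = target mean
    relaxed_frac_core = (0.0108 - 0.0022) / (0.5 - 0.0022),
    relaxed_frac_noncore = NA_real_,  # filled below from the all-genes mean
    species_sdlog = species_sdlog)
  f <- cfg$core_fraction
  target_noncore <- (0.0221 - f * 0.0108) / (1 - f)
  cfg$calibration$relaxed_frac_noncore <-
    (target_noncore - 0.0022) / (0.5 - 0.0022)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_species >= 0,
            cfg$genes_per_species >= 0,
            cfg$individuals_per_species >= 1)
  for (f in c("core_fraction", "coverage_dropout", "minus_strand_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(sprintf("%s must be in [0, 1]", f), call. = FALSE)
  if (cfg$gene_length_nt %% 3L != 0L || cfg$gene_length_nt < 303L)
    stop("gene_length_nt must be divisible by 3 and >= 303 (100 aa + stop)",
         call. = FALSE)
  if (cfg$mu_lof_per_gene < 0 || cfg$mu_lof_per_gene > 1)
    stop("mu_lof_per_gene must be a rate in [0, 1]", call. = FALSE)
  if (cfg$mu_lof_per_gene > 0 && cfg$sel_coeff <= 0)
    stop("equilibrium q = u/s undefined: sel_coeff must be > 0 when u > 0",
         call. = FALSE)
  if (length(cfg$fecundity_range) != 2L ||
      any(cfg$fecundity_range <= 0) || diff(cfg$fecundity_range) < 0)
    stop("fecundity_range must be positive and increasing", call. = FALSE)
  if (any(cfg$type_weights < 0) || sum(cfg$type_weights) <= 0)
    stop("type_weights must be non-negative and sum > 0", call. = FALSE)
  invisible(cfg)
}

# deterministic derived seed, kept below 2^31 - 1
derive_seed <- function(root, index) {
  as.integer((as.double(root) * 48271 + as.double(index) * 1117) %% 2147483647)
}

PHYLA <- c("Chordata", "Arthropoda", "Mollusca", "Annelida",
           "Echinodermata", "Cnidaria")

STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(
  as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0),
                  c("A", "C", "G", "T"), paste0)),
  STOP_CODONS)

#' Build a synthetic species panel
#'
#' Draws species fecundities log-uniformly, derives per-species selection
#' coefficients \eqn{s_i = s (F_i/F_{ref})^\beta}, sets per-gene equilibrium
#' allele frequencies q = min(1, u / s_i) (or the calibration mixture), builds
#' a correlated life-history trait table, and (optionally) designs one
#' reference transcript per gene: random UTRs around a single complete ORF
#' (ATG, sense codons, in-frame stop) of the configured length, on the plus or
#' minus strand.
#'
#' @param config an `lof_sim_config` from [simulation_config()].
#' @param build_sequences if `FALSE`, skip transcript sequences (fast path for
#'   purely statistical simulation; no variants can be synthesised then).
#' @return an object of class `lof_panel`: a list with `config`, `species`
#'   (trait table), `genes` (gene table with core flags), `q` (genes x species
#'   matrix of allele frequencies), and per-species `transcripts` (sequence
#'   character vectors) plus `orfs` (designed ORF table) when sequences are
#'   built.
#' @export
build_species_panel <- function(config, build_sequences = TRUE) {
  validate_sim_config(config)
  set.seed(config$seed)
  S <- config$n_species
  G <- config$genes_per_species
  if (S == 0L) {
    panel <- list(config = config,
                  species = empty_species_table(),
                  genes = data.frame(gene_id = character(), core = logical()),
                  q = matrix(numeric(), nrow = G, ncol = 0),
                  transcripts = list(), orfs = list(), manifest = character())
    class(panel) <- "lof_panel"
    return(panel)
  }

  species_id <- sprintf("sp%02d", seq_len(S))
  fr <- config$fecundity_range
  fec <- exp(stats::runif(S, log(fr[1]), log(fr[2])))
  f_ref <- sqrt(fr[1] * fr[2])
  s_i <- config$sel_coeff * (fec / f_ref)^config$coupling_beta
  species <- make_trait_table(species_id, fec)
  species$s_i <- s_i

  gene_id <- sprintf("g%05d", seq_len(G))
  n_core <- round(config$core_fraction * G)
  core <- logical(G)
  core[sample.int(G, n_core)] <- TRUE
  genes <- data.frame(gene_id = gene_id, core = core,
                      stringsAsFactors = FALSE)

  if (config$q_model == "calibration") {
    cal <- config$calibration
    relaxed <- ifelse(core,
                      stats::runif(G) < cal$relaxed_frac_core,
                      stats::runif(G) < cal$relaxed_frac_noncore)
    q_gene <- ifelse(relaxed,
                     stats::runif(G, cal$q_relaxed_range[1],
                                  cal$q_relaxed_range[2]),
                     cal$q_constrained)
    genes$relaxed <- relaxed
    sdl <- cal$species_sdlog
    c_i <- stats::rlnorm(S, meanlog = -sdl^2 / 2, sdlog = sdl)
    q <- outer(q_gene, c_i)
    q[q > 1] <- 1
  } else {
    s_gene <- if (config$s_jitter_sd > 0) {
      stats::rlnorm(G, meanlog = -config$s_jitter_sd^2 / 2,
                    sdlog = config$s_jitter_sd)
    } else rep(1, G)
    q <- config$mu_lof_per_gene / outer(s_gene, s_i)
    q[q > 1] <- 1
  }
  dimnames(q) <- list(gene_id, species_id)

  panel <- list(config = config, species = species, genes = genes, q = q,
                transcripts = list(), orfs = list())
  if (build_sequences && G > 0) {
    for (i in seq_len(S)) {
      set.seed(derive_seed(config$seed, i))
      ts <- design_transcripts(gene_id, config)
      panel$transcripts[[species_id[i]]] <- ts$seq
      panel$orfs[[species_id[i]]] <- ts$orfs
    }
  }
  class(panel) <- "lof_panel"
  panel
}

empty_species_table <- function() {
  data.frame(species_id = character(), phylum = character(),
             adult_size = numeric(), body_mass = numeric(),
             longevity = numeric(), lifetime_fecundity = numeric(),
             propagule_size = numeric(), genome_size = numeric(),
             pi_s = numeric(), haplodiploid = logical(),
             stringsAsFactors = FALSE)
}

# Life-history traits as noisy monotone transforms of fecundity on the log
# scale: long-lived, large, heavy species have few offspring and large
# propagules; pi_s rises with fecundity (fecund species tend to have larger
# effective population sizes).
make_trait_table <- function(species_id, fec) {
  S <- length(species_id)
  lf <- log(fec) - mean(log(fec))
  longevity <- exp(2.0 - 0.35 * lf + stats::rnorm(S, 0, 0.5))      # years
  adult_size <- exp(1.5 - 0.25 * lf + stats::rnorm(S, 0, 0.6))     # cm
  body_mass <- exp(3 * log(adult_size) - 2 + stats::rnorm(S, 0, 0.7)) # g
  propagule <- exp(0.3 - 0.4 * lf + stats::rnorm(S, 0, 0.6))       # mm
  genome <- exp(stats::rnorm(S, log(1000), 0.5))                   # Mb
  pi_s <- pmin(0.2, 0.01 * exp(0.3 * lf + stats::rnorm(S, 0, 0.4)))
  genome[stats::runif(S) < 0.15] <- NA
  pi_s[stats::runif(S) < 0.10] <- NA
  data.frame(species_id = species_id,
             phylum = rep_len(PHYLA, S),
             adult_size = adult_size, body_mass = body_mass,
             longevity = longevity, lifetime_fecundity = fec,
             propagule_size = propagule, genome_size = genome,
             pi_s = pi_s, haplodiploid = FALSE,
             stringsAsFactors = FALSE)
}

# One transcript per gene: UTR5 + [ATG, sense codons, stop] + UTR3, possibly
# stored reverse-complemented. Designed ORF coordinates are 1-based inclusive
# on the stored (forward) sequence.
design_transcripts <- function(gene_id, config) {
  G <- length(gene_id)
  n_cod <- config$gene_length_nt %/% 3L
  inner <- matrix(sample(SENSE_CODONS, G * (n_cod - 2L), replace = TRUE),
                  nrow = n_cod - 2L)
  stop_cod <- sample(STOP_CODONS, G, replace = TRUE)
  cds <- paste0("ATG",
                apply(inner, 2, paste0, collapse = ""),
                stop_cod)
  u5 <- sample(config$utr_range[1]:config$utr_range[2], G, replace = TRUE)
  u3 <- sample(config$utr_range[1]:config$utr_range[2], G, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  rand_nt <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
  utr5 <- vapply(u5, rand_nt, character(1))
  utr3 <- vapply(u3, rand_nt, character(1))
  seqs <- paste0(utr5, cds, utr3)
  L <- nchar(seqs)
  cds_start <- u5 + 1L
  cds_end <- u5 + config$gene_length_nt
  strand <- ifelse(stats::runif(G) < config$minus_strand_fraction, "-", "+")
  flip <- strand == "-"
  seqs[flip] <- revcomp(seqs[flip])
  new_start <- ifelse(flip, L - cds_end + 1L, cds_start)
  new_end <- ifelse(flip, L - cds_start + 1L, cds_end)
  orfs <- data.frame(transcript_id = gene_id,
                     cds_start = as.integer(new_start),
                     cds_end = as.integer(new_end),
                     strand = strand,
                     protein_length_aa = n_cod - 1L,
                     stringsAsFactors = FALSE)
  names(seqs) <- gene_id
  list(seq = seqs, orfs = orfs)
}

#' Expected LoF allele proportion of a gene set
#'
#' Under Hardy-Weinberg genotype sampling the expectation of the per-individual
#' statistic \eqn{p = (N_{het} + 2 N_{hom}) / (2N)} restricted to a gene set is
#' the mean allele frequency over that set, averaged over species.
#'
#' @param panel an `lof_panel`.
#' @param gene_set `"all"`, `"core"`, or `"noncore"`; or a character vector of
#'   gene IDs (e.g. a realized hard-core set).
#' @param by_species return the per-species vector instead of the grand mean.
#' @return a fraction (or named vector if `by_species`).
#' @export
expected_lof_proportion <- function(panel, gene_set = "all",
                                    by_species = FALSE) {
  stopifnot(inherits(panel, "lof_panel"))
  ids <- if (length(gene_set) == 1L && gene_set %in%
             c("all", "core", "noncore")) {
    switch(gene_set,
           all = panel$genes$gene_id,
           core = panel$genes$gene_id[panel$genes$core],
           noncore = panel$genes$gene_id[!panel$genes$core])
  } else if (is.character(gene_set)) {
    missing_ids <- setdiff(gene_set, panel$genes$gene_id)
    if (length(missing_ids))
      stop("unknown gene IDs in gene_set: ", paste(utils::head(missing_ids, 3),
                                                   collapse = ", "))
    gene_set
  } else stop("unknown gene-set label")
  if (length(ids) == 0L) return(NA_real_)
  per_sp <- colMeans(panel$q[ids, , drop = FALSE])
  if (by_species) per_sp else mean(per_sp)
}

#' Draw per-individual genotypes and synthesize variant calls
#'
#' For every gene and individual, a diploid LoF genotype is drawn under
#' Hardy-Weinberg: hom with probability \eqn{q_g^2}, het with
#' \eqn{2 q_g (1 - q_g)}. Each carrier gene receives one concrete variant
#' (stopgain / frameshift / stoploss by `type_weights`) placed in the designed
#' CDS, with depth ~ Poisson(depth_mean) and uniform phred qualities; a
#' `coverage_dropout` fraction of ORFs per individual is marked not fully
#' sequenced. Identical seeds give identical output.
#'
#' @param panel an `lof_panel` (with sequences for variant synthesis; without,
#'   only genotypes and coverage are returned).
#' @param seed integer; defaults to the panel's root seed.
#' @return a list of class `lof_genotypes` with data frames `profiles`
#'   (per-individual QC metrics), `coverage` (gene x individual depth summary),
#'   `genotypes` (LoF carrier genes, sparse) and `variants` (VCF-shaped calls).
#' @export
sample_individual_genotypes <- function(panel, seed = panel$config$seed) {
  stopifnot(inherits(panel, "lof_panel"))
  cfg <- panel$config
  has_seq <- length(panel$transcripts) > 0
  profs <- list(); covs <- list(); genos <- list(); vars <- list()
  k <- 0L
  for (sp in panel$species$species_id) {
    qv <- panel$q[, sp]
    for (j in seq_len(cfg$individuals_per_species)) {
      k <- k + 1L
      ind <- sprintf("%s_i%02d", sp, j)
      set.seed(derive_seed(seed, k * 7L + 3L))
      G <- length(qv)
      u <- stats::runif(G)
      state <- ifelse(u < qv^2, "hom",
                      ifelse(u < qv^2 + 2 * qv * (1 - qv), "het", "none"))
      dropped <- stats::runif(G) < cfg$coverage_dropout
      min_depth <- integer(G)
      min_depth[dropped] <- sample(0:5, sum(dropped), replace = TRUE)
      min_depth[!dropped] <- 6L + stats::rpois(sum(!dropped),
                                               cfg$depth_mean / 2)
      covs[[k]] <- data.frame(species_id = sp, individual_id = ind,
                              gene_id = panel$genes$gene_id,
                              min_cds_depth = min_depth,
                              stringsAsFactors = FALSE)
      carriers <- which(state != "none")
      if (length(carriers)) {
        genos[[k]] <- data.frame(species_id = sp, individual_id = ind,
                                 gene_id = panel$genes$gene_id[carriers],
                                 zygosity = state[carriers],
                                 stringsAsFactors = FALSE)
      }
      if (has_seq) {
        vars[[k]] <- synth_variants(panel, sp, ind, carriers, state, cfg)
      }
      profs[[k]] <- data.frame(
        individual_id = ind, species_id = sp,
        mean_coverage = round(cfg$depth_mean * stats::runif(1, 0.8, 1.2), 1),
        alignment_rate = round(stats::runif(1, 0.85, 0.98), 3),
        n_covered_orfs = G,
        n_covered_core = sum(panel$genes$core),
        stringsAsFactors = FALSE)
    }
  }
  out <- list(profiles = do.call(rbind, profs),
              coverage = do.call(rbind, covs),
              genotypes = if (length(genos)) do.call(rbind, genos) else
                data.frame(species_id = character(), individual_id = character(),
                           gene_id = character(), zygosity = character()),
              variants = if (length(vars)) do.call(rbind, vars) else NULL)
  class(out) <- "lof_genotypes"
  out
}

# Concrete variants for LoF carrier genes plus background random SNVs.
synth_variants <- function(panel, sp, ind, carriers, state, cfg) {
  seqs <- panel$transcripts[[sp]]
  orfs <- panel$orfs[[sp]]
  rows <- list()
  tw <- cfg$type_weights / sum(cfg$type_weights)
  if (length(carriers)) {
    types <- sample(names(tw), length(carriers), replace = TRUE, prob = tw)
    for (m in seq_along(carriers)) {
      g <- carriers[m]
      orf <- orfs[g, ]
      v <- make_lof_variant(seqs[[g]], orf, types[m])
      if (is.null(v)) next
      rows[[length(rows) + 1L]] <- data.frame(
        species_id = sp, individual_id = ind,
        transcript_id = orf$transcript_id,
        pos = v$pos, ref = v$ref, alt = v$alt,
        zygosity = state[g],
        depth = stats::rpois(1, cfg$depth_mean),
        variant_qual = round(stats::runif(1, 30, 60)),
        mapping_qual = round(stats::runif(1, 30, 60)),
        stringsAsFactors = FALSE)
    }
  }
  n_bg <- stats::rbinom(1, length(seqs), cfg$background_var_rate)
  if (n_bg > 0) {
    bg_genes <- sample(seq_along(seqs), n_bg)
    for (g in bg_genes) {
      s <- seqs[[g]]
      # background SNVs are non-LoF by construction (synonymous, missense or
      # noncoding): the LoF process is governed entirely by q
      repeat {
        pos <- sample.int(nchar(s), 1)
        ref <- substr(s, pos, pos)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
        if (!snv_touches_stop(s, orfs[g, ], pos, alt)) break
      }
      rows[[length(rows) + 1L]] <- data.frame(
        species_id = sp, individual_id = ind,
        transcript_id = orfs$transcript_id[g],
        pos = pos, ref = ref, alt = alt,
        zygosity = sample(c("het", "hom"), 1, prob = c(0.8, 0.2)),
        depth = stats::rpois(1, cfg$depth_mean),
        variant_qual = round(stats::runif(1, 30, 60)),
        mapping_qual = round(stats::runif(1, 30, 60)),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

# TRUE when a substitution creates or destroys a stop codon of the designed
# ORF (i.e. would be stopgain or stoploss). Used to keep background variants
# non-LoF.
snv_touches_stop <- function(s, orf, pos, alt) {
  if (pos < orf$cds_start || pos > orf$cds_end) return(FALSE)
  minus <- orf$strand == "-"
  off <- if (minus) orf$cds_end - pos else pos - orf$cds_start
  k <- off %/% 3L
  rng <- if (minus) c(orf$cds_end - k * 3L - 2L, orf$cds_end - k * 3L)
         else c(orf$cds_start + k * 3L, orf$cds_start + k * 3L + 2L)
  ref_codon <- substr(s, rng[1], rng[2])
  alt_codon <- ref_codon
  substr(alt_codon, pos - rng[1] + 1L, pos - rng[1] + 1L) <- alt
  if (minus) {
    ref_codon <- revcomp(ref_codon)
    alt_codon <- revcomp(alt_codon)
  }
  (ref_codon %in% STOP_CODONS) || (alt_codon %in% STOP_CODONS)
}

# Single-edit tables: for each sense codon, the single-base edits that create a
# stop; for each stop codon, the edits that destroy it.
codon_stop_edits <- local({
  tab <- list()
  for (cod in SENSE_CODONS) {
    hits <- list()
    for (p in 1:3) for (b in c("A", "C", "G", "T")) {
      if (substr(cod, p, p) == b) next
      mut <- cod
      substr(mut, p, p) <- b
      if (mut %in% STOP_CODONS)
        hits[[length(hits) + 1L]] <- list(offset = p, alt = b)
    }
    tab[[cod]] <- hits
  }
  tab
})

# Place one LoF variant of the requested type in the designed CDS.
# Coordinates are on the stored forward sequence; codon arithmetic is done on
# the ORF strand and mapped back.
make_lof_variant <- function(s, orf, type) {
  w <- orf$cds_end - orf$cds_start + 1L
  n_cod <- w %/% 3L
  minus <- orf$strand == "-"
  codon_fwd <- function(k) {  # k: 1-based codon index in reading direction
    if (!minus) {
      st <- orf$cds_start + (k - 1L) * 3L
      c(st, st + 2L)
    } else {
      en <- orf$cds_end - (k - 1L) * 3L
      c(en - 2L, en)
    }
  }
  get_codon <- function(k) {
    rng <- codon_fwd(k)
    cod <- substr(s, rng[1], rng[2])
    if (minus) revcomp(cod) else cod
  }
  emit_snv <- function(k, offset, alt_base) {
    rng <- codon_fwd(k)
    pos <- if (!minus) rng[1] + offset - 1L else rng[2] - offset + 1L
    ref <- substr(s, pos, pos)
    alt <- if (minus) revcomp(alt_base) else alt_base
    if (ref == alt) return(NULL)
    list(pos = pos, ref = ref, alt = alt)
  }
  if (type == "stopgain") {
    for (k in sample(seq_len(n_cod - 1L))) {
      hits <- codon_stop_edits[[get_codon(k)]]
      if (length(hits)) {
        h <- hits[[sample.int(length(hits), 1)]]
        return(emit_snv(k, h$offset, h$alt))
      }
    }
    NULL
  } else if (type == "stoploss") {
    cod <- get_codon(n_cod)
    repeat {
      p <- sample.int(3L, 1)
      b <- sample(c("A", "C", "G", "T"), 1)
      mut <- cod
      substr(mut, p, p) <- b
      if (mut != cod && !(mut %in% STOP_CODONS))
        return(emit_snv(n_cod, p, b))
    }
  } else if (type == "frameshift") {
    if (stats::runif(1) < 0.5) {  # 1-bp deletion
      pos <- sample(orf$cds_start:(orf$cds_end - 1L), 1)
      list(pos = pos, ref = substr(s, pos, pos + 1L),
           alt = substr(s, pos, pos))
    } else {                      # 1-bp insertion
      pos <- sample(orf$cds_start:(orf$cds_end - 1L), 1)
      ref <- substr(s, pos, pos)
      list(pos = pos, ref = ref, alt = paste0(ref, sample(c("A", "C", "G", "T"), 1)))
    }
  } else stop("unknown variant type: ", type)
}
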