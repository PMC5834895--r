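# Spearman rank correlations of species-mean LoF proportions against
# life-history traits, with Benjamini-Hochberg correction over the grid.

#' Spearman rank correlation with t-approximation p-value
#'
#' Midrank (average-rank) Spearman rho; the two-sided p-value comes from
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on n - 2 degrees of freedom,
#' \eqn{|\rho| = 1} giving p = 0. Pairs with a missing value in either vector
#' are dropped first (pairwise deletion, no imputation).
#'
#' @param x,y numeric vectors of equal length.
#' @return a list with `n`, `rho`, `p`, and `reason` (`NA` unless the test is
#'   undefined: fewer than 3 complete pairs, or zero variance).
#' @export
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L)
    return(list(n = n, rho = NA_real_, p = NA_real_, reason = "n < 3"))
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(list(n = n, rho = NA_real_, p = NA_real_, reason = "zero variance"))
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(n = n, rho = rho, p = p, reason = NA_character_)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR correction (`stats::p.adjust` method `"BH"`) with input
#' validation; missing entries pass through untouched and do not count toward
#' the family size.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Correlation grid over measures and traits
#'
#' Computes [spearman_test()] for every unordered pair among the chosen
#' measure and trait columns of a species table (measure-trait and
#' trait-trait; self-pairs are omitted) and BH-adjusts over all tests in the
#' emitted grid. Significance is called at alpha on the adjusted p-value.
#'
#' @param records species-level data frame (one row per species).
#' @param measures,traits column names to correlate.
#' @param alpha significance level on `p_bh`.
#' @return long data frame: `x`, `y`, `n`, `rho`, `p_raw`, `p_bh`,
#'   `significant`.
#' @export
correlation_matrix <- function(records,
                               measures = c("p_all", "p_core", "p_hardcore"),
                               traits = c("adult_size", "body_mass",
                                          "longevity", "lifetime_fecundity",
                                          "propagule_size", "genome_size",
                                          "pi_s"),
                               alpha = 0.05) {
  vars <- c(measures, traits)
  missing_cols <- setdiff(vars, names(records))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(records) < 3L) stop("need at least 3 species")
  pairs <- utils::combn(vars, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    st <- spearman_test(records[[a]], records[[b]])
    data.frame(x = a, y = b, n = st$n, rho = st$rho, p_raw = st$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- bh_adjust(out$p_raw)
  out$significant <- !is.na(out$p_bh) & out$p_bh < alpha
  out
}

#' Read a species trait table
#'
#' TSV with columns `species_id`, `phylum`, `adult_size`, `body_mass`,
#' `longevity`, `lifetime_fecundity`, `propagule_size`, `genome_size`, `pi_s`,
#' `haplodiploid` (missing values as `NA` or empty).
#'
#' @param path file path.
#' @return data frame.
#' @export
read_species_traits <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  required <- c("species_id", "phylum", "adult_size", "body_mass", "longevity",
                "lifetime_fecundity", "propagule_size", "genome_size", "pi_s",
                "haplodiploid")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    stop("trait table lacks columns: ", paste(missing_cols, collapse = ", "))
  d$haplodiploid <- as.logical(d$haplodiploid)
  d
}
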