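# Are pseudogenes distributed non-randomly across COG functional
# categories? Pearson chi-squared statistic over a categories x
# {intact, pseudogene} table, Monte-Carlo simulated p-value from label
# permutation (both margins fixed), and per-cell Pearson residuals.

#' Build the COG contingency table
#'
#' Rows are the COG categories present among the coding features; columns
#' are intact vs pseudogene counts. Features without a category are
#' excluded and their number reported in the `excluded` attribute.
#'
#' @param features a [feature_set()] carrying final call status (ftype CDS
#'   vs pseudogene) and COG labels.
#' @return matrix with columns `intact`, `pseudo`; attribute `excluded`.
#' @export
build_cog_table <- function(features) {
  coding <- features[features$ftype %in% c("CDS", "pseudogene"), , drop = FALSE]
  has_cog <- !is.na(coding$cog_category)
  excluded <- sum(!has_cog)
  coding <- coding[has_cog, , drop = FALSE]
  cats <- sort(unique(coding$cog_category))
  if (length(cats) < 2)
    stop_validation("need at least 2 COG categories with counts; got ",
                    length(cats))
  tab <- cbind(
    intact = vapply(cats, function(k)
      sum(coding$cog_category == k & coding$ftype == "CDS"), 1L),
    pseudo = vapply(cats, function(k)
      sum(coding$cog_category == k & coding$ftype == "pseudogene"), 1L))
  rownames(tab) <- cats
  attr(tab, "excluded") <- excluded
  tab
}

#' Pearson chi-squared statistic of a categories x 2 table
#'
#' statistic = sum over cells of (observed - expected)^2 / expected, with
#' expected counts from the products of the margins; df = number of
#' categories - 1.
#'
#' @param table numeric matrix, categories x 2.
#' @return list(statistic, df, expected, residuals); residuals are the
#'   signed Pearson residuals (obs - exp) / sqrt(exp) per cell.
#' @export
pearson_chisq <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop_validation("negative counts")
  if (any(colSums(table) == 0))
    stop_validation("degenerate table: a column total is zero")
  grand <- sum(table)
  expected <- outer(rowSums(table), colSums(table)) / grand
  residuals <- (table - expected) / sqrt(expected)
  list(statistic = sum(residuals^2), df = nrow(table) - 1L,
       expected = expected, residuals = residuals)
}

# Chi-squared statistics of B label permutations. Category sizes and the
# intact/pseudo totals are fixed in every replicate, i.e. the null
# conditions on both margins.
.permute_statistics <- function(table, B) {
  cat_sizes <- rowSums(table)
  n_pseudo <- sum(table[, "pseudo"])
  g <- rep(seq_len(nrow(table)), cat_sizes)
  n <- length(g)
  grand <- sum(table)
  exp_pseudo <- cat_sizes * n_pseudo / grand
  exp_intact <- cat_sizes * (grand - n_pseudo) / grand
  vapply(seq_len(B), function(b) {
    lab <- sample.int(n, n_pseudo)
    obs_pseudo <- tabulate(g[lab], nbins = nrow(table))
    sum((obs_pseudo - exp_pseudo)^2 / exp_pseudo) +
      sum((cat_sizes - obs_pseudo - exp_intact)^2 / exp_intact)
  }, numeric(1))
}

#' Monte-Carlo simulated p-value for the COG chi-squared test
#'
#' Null replicates are generated by randomly permuting the intact/pseudo
#' labels across all genes while keeping each category's gene count fixed
#' (both margins conditioned). The p-value uses the add-one estimator
#' p = (b + 1) / (B + 1) where b counts replicate statistics at least as
#' large as the observed one; it is never exactly zero and its floor at
#' B = 2000 is 1/2001 = 0.0004998.
#'
#' @param table matrix from [build_cog_table()].
#' @param B number of Monte-Carlo replicates.
#' @param seed integer seed (mandatory for reproducibility).
#' @return object of class `cog_chisq`: statistic, df, B, b_exceed,
#'   p_simulated, residuals (pseudogene column), residual matrix, seed.
#' @export
simulated_pvalue <- function(table, B = 2000L, seed = 1L) {
  if (B < 1) stop_validation("B must be at least 1")
  obs <- pearson_chisq(table)
  set.seed(seed)
  sims <- .permute_statistics(table, B)
  b_exceed <- sum(sims >= obs$statistic - 1e-12)
  structure(list(statistic = obs$statistic, df = obs$df, B = as.integer(B),
                 b_exceed = b_exceed,
                 p_simulated = (b_exceed + 1) / (B + 1),
                 residuals = obs$residuals[, "pseudo"],
                 residual_matrix = obs$residuals,
                 expected = obs$expected, table = table,
                 seed = as.integer(seed)),
            class = "cog_chisq")
}

#' @export
print.cog_chisq <- function(x, ...) {
  cat(sprintf(
    "Pearson's Chi-squared test with simulated p-value (based on %d replicates)\n",
    x$B))
  cat(sprintf("  X-squared = %.4g, df = %d, p-value = %.4g\n",
              x$statistic, x$df, x$p_simulated))
  invisible(x)
}

#' Categories ordered by pseudogene overrepresentation
#'
#' Positive residuals mean the category holds more pseudogenes than
#' expected under independence.
#'
#' @param result a [simulated_pvalue()] result.
#' @return data.frame (category, residual) sorted by decreasing residual of
#'   the pseudogene column.
#' @export
residual_report <- function(result) {
  r <- sort(result$residuals, decreasing = TRUE)
  data.frame(category = names(r), residual = unname(r))
}

# category, counts, percent pseudo and residual for cog_table.tsv.
cog_table_report <- function(result) {
  tab <- result$table
  data.frame(category = rownames(tab),
             n_intact = tab[, "intact"], n_pseudo = tab[, "pseudo"],
             pct_pseudo = round(100 * tab[, "pseudo"] / rowSums(tab), 1),
             residual = round(result$residuals, 4),
             row.names = NULL)
}
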