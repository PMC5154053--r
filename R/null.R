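#' Permute phenotype labels
#'
#' Uniform random permutation of the case/control labels; class totals are
#' conserved and genotypes are untouched. Draws from the current RNG stream.
#'
#' @param phenotype Character vector of `"case"`/`"control"`.
#' @return Permuted phenotype vector.
#' @export
permute_phenotype <- function(phenotype) {
  if (length(phenotype) < 2L) stop("need >= 2 samples", call. = FALSE)
  phenotype[sample.int(length(phenotype))]
}

#' Build a permutation null distribution of the pairwise MDR statistic
#'
#' For each of `n_permutations` label permutations the whole pairwise scan is
#' rerun (labels permuted once per round and shared by all pairs, preserving
#' the between-pair dependence). In `"pooled"` mode every pair's statistic
#' from every permutation enters the null; in `"max"` mode only each
#' permutation's maximum over all pairs is kept, giving a family-wise null
#' that calibrates best-pair selections.
#'
#' @param cohort A [cohort_data].
#' @param n_permutations Number of permutation rounds (>= 1); 1000 matches a
#'   conventional 1000-fold permutation test.
#' @param mode `"pooled"` or `"max"`.
#' @param seed Integer seed; the null is a pure function of
#'   (cohort, n_permutations, mode, seed).
#' @param maf_min Passed through to the scan's optional MAF filter.
#' @return Object of class `mdr_null`: list with sorted `values`,
#'   `n_permutations`, `mode`, `seed` and `n_pairs`.
#' @export
build_null <- function(cohort, n_permutations = 1000L,
                       mode = c("pooled", "max"), seed = 1L, maf_min = 0) {
  stopifnot(inherits(cohort, "cohort_data"))
  mode <- match.arg(mode)
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 1L) stop("n_permutations must be >= 1", call. = FALSE)

  G <- cohort$genotypes
  if (maf_min > 0) G <- G[, snp_maf(G) >= maf_min, drop = FALSE]
  if (ncol(G) < 2L) stop("need at least 2 SNPs", call. = FALSE)
  ind <- make_indicators(G)
  tot_cc <- cross_counts(ind)
  n_tot <- pair_totals(ind)
  ycase <- as.double(cohort$phenotype == "case")
  ut <- upper.tri(matrix(0, ncol(G), ncol(G)))
  n_pairs <- sum(ut)

  set.seed(seed, kind = "Mersenne-Twister")
  values <- if (mode == "pooled") numeric(n_permutations * n_pairs)
            else numeric(n_permutations)
  for (r in seq_len(n_permutations)) {
    yperm <- ycase[sample.int(length(ycase))]
    ba <- scan_engine(ind, tot_cc, n_tot, yperm)[ut]
    ba <- ba[is.finite(ba)]
    if (mode == "pooled") {
      values[(r - 1L) * n_pairs + seq_along(ba)] <- ba
      if (length(ba) < n_pairs)
        values[(r - 1L) * n_pairs + seq.int(length(ba) + 1L, n_pairs)] <- NA_real_
    } else {
      values[r] <- max(ba)
    }
  }
  values <- sort(values[!is.na(values)])
  structure(list(values = values, n_permutations = n_permutations,
                 mode = mode, seed = as.integer(seed), n_pairs = n_pairs),
            class = "mdr_null")
}

#' @export
print.mdr_null <- function(x, ...) {
  cat(sprintf("<mdr_null mode='%s'>  %d permutations, %d pairs, %d null values\n",
              x$mode, x$n_permutations, x$n_pairs, length(x$values)))
  cat(sprintf("  quantiles: 50%% %.4f  95%% %.4f  max %.4f\n",
              stats::quantile(x$values, .5), stats::quantile(x$values, .95),
              max(x$values)))
  invisible(x)
}

#' Empirical permutation p-value
#'
#' Add-one estimator `p = (1 + #{null >= observed}) / (1 + N)`, so `p > 0`
#' always and `p` is monotone non-increasing in the observed statistic.
#'
#' @param observed Numeric vector of observed statistics.
#' @param null An `mdr_null` from [build_null()], or a numeric vector of null
#'   statistics.
#' @return Numeric vector of p-values in (0, 1\].
#' @export
empirical_pvalue <- function(observed, null) {
  values <- if (inherits(null, "mdr_null")) null$values else sort(as.numeric(null))
  if (!length(values)) stop("null distribution is empty", call. = FALSE)
  n_ge <- length(values) - findInterval(observed, values, left.open = TRUE)
  (1 + n_ge) / (1 + length(values))
}

#' Per-SNP p-values from pair results
#'
#' Each SNP receives the minimum p-value over all pairs containing it (its
#' strongest pairwise association); ties are broken by the smallest partner
#' id. When every pair is scored against one shared null this equals the
#' p-value of the SNP's best statistic.
#'
#' @param pair_results `mdr_pairs` data frame carrying a `p_value` column.
#' @param snps Optional SNP map; SNPs appearing in no surviving pair are
#'   reported with a message.
#' @return Data frame with columns `snp_id`, `p_value`, `statistic`, `partner`.
#' @export
assign_snp_pvalues <- function(pair_results, snps = NULL) {
  if (!"p_value" %in% names(pair_results))
    stop("pair_results must carry a p_value column (run empirical_pvalue first)",
         call. = FALSE)
  long <- data.frame(snp_id = c(pair_results$snp_i, pair_results$snp_j),
                     partner = c(pair_results$snp_j, pair_results$snp_i),
                     statistic = rep(pair_results$statistic, 2L),
                     p_value = rep(pair_results$p_value, 2L),
                     stringsAsFactors = FALSE)
  long <- long[order(long$snp_id, long$p_value, -long$statistic, long$partner), ]
  out <- long[!duplicated(long$snp_id),
              c("snp_id", "p_value", "statistic", "partner")]
  rownames(out) <- NULL
  if (!is.null(snps)) {
    missing <- setdiff(snps$snp_id, out$snp_id)
    if (length(missing))
      message(length(missing), " SNP(s) appear in no surviving pair: ",
              paste(utils::head(missing, 3L), collapse = ", "))
  }
  out
}

#' Pairwise MDR scan with permutation significance
#'
#' The package's main fitting-style entry point for Phase I: runs the
#' exhaustive pairwise scan, builds a permutation null, attaches empirical
#' p-values to every pair and assigns each SNP the p-value of its strongest
#' pairwise association.
#'
#' The default null is the per-permutation maximum (`mode = "max"`): because a
#' SNP's p-value is the best over all its pairs, it must be calibrated against
#' the same best-of selection under the null, otherwise essentially every SNP
#' clears a fixed significance level. `mode = "pooled"` scores each pair
#' against the pooled per-pair null and is appropriate for pair-level
#' inference.
#'
#' @param cohort A [cohort_data].
#' @param n_permutations Permutation rounds (default 1000).
#' @param mode `"max"` (default) or `"pooled"`; see Details.
#' @param seed Integer seed for the permutation stream.
#' @param maf_min Optional MAF filter (default 0 = off).
#' @return Object of class `mdr_scan`: list with `pairs` (pair results with
#'   p-values), `snps` (per-SNP best statistic and p-value), `null`
#'   (the [build_null()] object) and `cohort_id`.
#' @examples
#' sim <- simulate_cohort(sim_config(n_cases = 100, n_controls = 100,
#'                                   n_snps = 12, n_genes = 4, n_sets = 2,
#'                                   seed = 3))
#' fit <- mdr_scan(sim$cohort, n_permutations = 50, seed = 3)
#' summary(fit)
#' @export
mdr_scan <- function(cohort, n_permutations = 1000L,
                     mode = c("max", "pooled"), seed = 1L, maf_min = 0) {
  mode <- match.arg(mode)
  pairs <- pairwise_scan(cohort, maf_min = maf_min)
  null <- build_null(cohort, n_permutations = n_permutations, mode = mode,
                     seed = seed, maf_min = maf_min)
  pairs$p_value <- empirical_pvalue(pairs$statistic, null)
  snps <- assign_snp_pvalues(pairs, cohort$snps)
  structure(list(pairs = pairs, snps = snps, null = null,
                 cohort_id = cohort$cohort_id),
            class = "mdr_scan")
}

#' @export
print.mdr_scan <- function(x, ...) {
  cat(sprintf("<mdr_scan '%s'>  %d pairs, %d SNPs, %d permutations (%s null)\n",
              x$cohort_id, nrow(x$pairs), nrow(x$snps),
              x$null$n_permutations, x$null$mode))
  top <- x$pairs[order(x$pairs$p_value, -x$pairs$statistic), ][1L, ]
  cat(sprintf("  top pair: %s x %s  BA = %.4f  p = %.4g\n",
              top$snp_i, top$snp_j, top$statistic, top$p_value))
  invisible(x)
}

#' @export
summary.mdr_scan <- function(object, alpha = 0.05, ...) {
  structure(list(cohort_id = object$cohort_id,
                 n_pairs = nrow(object$pairs),
                 n_snps = nrow(object$snps),
                 n_permutations = object$null$n_permutations,
                 mode = object$null$mode,
                 alpha = alpha,
                 n_snps_sig = sum(object$snps$p_value <= alpha),
                 top_pairs = utils::head(
                   object$pairs[order(object$pairs$p_value,
                                      -object$pairs$statistic), ], 5L)),
            class = "summary.mdr_scan")
}

#' @export
print.summary.mdr_scan <- function(x, ...) {
  cat(sprintf("MDR pairwise scan of cohort '%s'\n", x$cohort_id))
  cat(sprintf("  %d pairs over %d SNPs; %d permutations, %s-statistic null\n",
              x$n_pairs, x$n_snps, x$n_permutations, x$mode))
  cat(sprintf("  SNPs with p <= %.3g: %d of %d\n", x$alpha, x$n_snps_sig,
              x$n_snps))
  cat("  top pairs:\n")
  print(x$top_pairs, row.names = FALSE)
  invisible(x)
}

#' Plot an MDR scan
#'
#' Histogram of the permutation null with the observed pair statistics
#' overlaid as a rug, a quick visual check of how far the leading pairs sit
#' above the null.
#'
#' @param x An `mdr_scan` object.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.mdr_scan <- function(x, ...) {
  graphics::hist(x$null$values, breaks = 40, freq = FALSE,
                 main = sprintf("Permutation null (%s) vs observed pairs",
                                x$null$mode),
                 xlab = "balanced accuracy",
                 xlim = range(c(x$null$values, x$pairs$statistic)), ...)
  graphics::rug(x$pairs$statistic, col = "red3")
  invisible(x)
}
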