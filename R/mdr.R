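#' Build the 3x3 case/control contingency table for a SNP pair
#'
#' Samples missing a genotype at either SNP are excluded (complete-case
#' analysis for this pair only).
#'
#' @param g_i,g_j Per-sample genotype codes 0/1/2 with `NA` for missing.
#' @param phenotype Character vector of `"case"`/`"control"`.
#' @return Object of class `pair_contingency`: list with 3x3 integer matrices
#'   `cases` and `controls` (rows = genotype at SNP i, columns at SNP j) and
#'   the complete-case totals `n_cases_used`, `n_controls_used`.
#' @export
build_contingency <- function(g_i, g_j, phenotype) {
  stopifnot(length(g_i) == length(g_j), length(g_i) == length(phenotype))
  keep <- !is.na(g_i) & !is.na(g_j)
  if (!any(keep))
    stop("degenerate pair: all samples excluded by missing genotypes",
         call. = FALSE)
  g_i <- g_i[keep]; g_j <- g_j[keep]; ph <- phenotype[keep]
  fi <- factor(g_i, levels = 0:2); fj <- factor(g_j, levels = 0:2)
  cases <- unclass(table(fi[ph == "case"], fj[ph == "case"]))
  controls <- unclass(table(fi[ph == "control"], fj[ph == "control"]))
  dimnames(cases) <- dimnames(controls) <- list(0:2, 0:2)
  structure(list(cases = cases, controls = controls,
                 n_cases_used = sum(cases), n_controls_used = sum(controls)),
            class = "pair_contingency")
}

#' Label multilocus genotype cells high/low risk
#'
#' The MDR constructive-induction step: a cell is `"high"` when its
#' case:control ratio is at least the threshold (ties go to high; a cell with
#' cases but no controls is high), `"low"` otherwise, and `"empty"` when it
#' holds no samples. The default threshold is the cohort's complete-case
#' case:control ratio, evaluated exactly by cross-multiplication so no
#' floating-point division is involved.
#'
#' @param table A [build_contingency()] result.
#' @param threshold Positive ratio; `NULL` (default) uses
#'   `n_cases_used / n_controls_used`.
#' @return 3x3 character matrix over `"high"`, `"low"`, `"empty"`.
#' @export
label_cells <- function(table, threshold = NULL) {
  stopifnot(inherits(table, "pair_contingency"))
  ca <- table$cases; co <- table$controls
  if (is.null(threshold)) {
    high <- ca * table$n_controls_used >= co * table$n_cases_used
  } else {
    if (!is.finite(threshold) || threshold <= 0)
      stop("threshold must be > 0", call. = FALSE)
    high <- ca >= threshold * co
  }
  lab <- matrix(ifelse(high, "high", "low"), 3L, 3L,
                dimnames = dimnames(ca))
  lab[ca + co == 0L] <- "empty"
  lab
}

#' Balanced accuracy of an MDR cell labelling
#'
#' Samples in high cells are predicted cases, samples in low cells controls;
#' empty cells hold no samples. Returns
#' `(sensitivity + specificity) / 2 = (TP/(TP+FN) + TN/(TN+FP)) / 2`.
#'
#' @param table A [build_contingency()] result.
#' @param labels 3x3 labelling from [label_cells()]; computed with the default
#'   threshold when omitted.
#' @return Balanced accuracy in \[0, 1\].
#' @export
balanced_accuracy <- function(table, labels = NULL) {
  stopifnot(inherits(table, "pair_contingency"))
  if (table$n_cases_used == 0L || table$n_controls_used == 0L)
    stop("degenerate pair: no usable cases or no usable controls", call. = FALSE)
  if (is.null(labels)) labels <- label_cells(table)
  sens <- sum(table$cases[labels == "high"]) / table$n_cases_used
  spec <- sum(table$controls[labels == "low"]) / table$n_controls_used
  (sens + spec) / 2
}

#' Evaluate a single SNP pair in full
#'
#' @param cohort A [cohort_data].
#' @param i,j SNP column indices or snp_ids.
#' @return Object of class `mdr_pair` with the contingency table, cell labels,
#'   balanced-accuracy `statistic` and sample counts.
#' @export
mdr_pair <- function(cohort, i, j) {
  stopifnot(inherits(cohort, "cohort_data"))
  if (is.character(i)) i <- match(i, cohort$snps$snp_id)
  if (is.character(j)) j <- match(j, cohort$snps$snp_id)
  if (anyNA(c(i, j))) stop("unknown snp_id", call. = FALSE)
  if (i > j) { k <- i; i <- j; j <- k }
  tab <- build_contingency(cohort$genotypes[, i], cohort$genotypes[, j],
                           cohort$phenotype)
  labels <- label_cells(tab)
  structure(list(snp_i = cohort$snps$snp_id[i],
                 snp_j = cohort$snps$snp_id[j],
                 contingency = tab, labels = labels,
                 statistic = balanced_accuracy(tab, labels)),
            class = "mdr_pair")
}

#' @export
print.mdr_pair <- function(x, ...) {
  cat(sprintf("<mdr_pair %s x %s>  balanced accuracy = %.4f  (n = %d/%d)\n",
              x$snp_i, x$snp_j, x$statistic,
              x$contingency$n_cases_used, x$contingency$n_controls_used))
  invisible(x)
}

# --- vectorised scan machinery -------------------------------------------
#
# All C(m,2) pairs are scored at once through nine m x m genotype
# cross-classification count matrices obtained as BLAS cross-products of 0/1
# indicator matrices. Counts are integers represented exactly in doubles, and
# the high/low rule is evaluated by cross-multiplication, so the result is
# bit-identical to the per-pair reference path.

make_indicators <- function(G) {
  X <- lapply(0:2, function(a) {
    M <- G == a
    M[is.na(M)] <- FALSE
    storage.mode(M) <- "double"
    M
  })
  has_na <- anyNA(G)
  obs <- if (has_na) X[[1L]] + X[[2L]] + X[[3L]] else NULL
  list(X = X, obs = obs, n = nrow(G), m = ncol(G))
}

# 3x3 list of m x m matrices: counts of samples (weighted by w in {0,1}) with
# genotype a-1 at SNP i and b-1 at SNP j; entry [[a]][[b]][i, j].
cross_counts <- function(ind, w = NULL) {
  X <- ind$X
  XL <- if (is.null(w)) X else lapply(X, function(M) M * w)
  cc <- vector("list", 3L)
  for (a in 1:3) cc[[a]] <- vector("list", 3L)
  for (a in 1:3) for (b in a:3) {
    M <- crossprod(XL[[a]], X[[b]])
    cc[[a]][[b]] <- M
    if (a != b) cc[[b]][[a]] <- t(M)
  }
  cc
}

# Complete-case totals per pair; collapses to a scalar when nothing is missing.
pair_totals <- function(ind, w = NULL) {
  if (is.null(ind$obs)) {
    if (is.null(w)) ind$n else sum(w)
  } else {
    O <- if (is.null(w)) ind$obs else ind$obs * w
    crossprod(O, ind$obs)
  }
}

# Balanced-accuracy matrix over all ordered pairs given case and total counts.
ba_matrix <- function(case_cc, tot_cc, n_case, n_ctrl) {
  sensN <- 0; specN <- 0
  for (a in 1:3) for (b in 1:3) {
    ca <- case_cc[[a]][[b]]
    ct <- tot_cc[[a]][[b]] - ca
    high <- ca * n_ctrl >= ct * n_case
    sensN <- sensN + ca * high
    specN <- specN + ct * !high
  }
  0.5 * (sensN / n_case + specN / n_ctrl)
}

scan_engine <- function(ind, tot_cc, n_tot, ycase) {
  case_cc <- cross_counts(ind, ycase)
  n_case <- pair_totals(ind, ycase)
  n_ctrl <- n_tot - n_case
  ba_matrix(case_cc, tot_cc, n_case, n_ctrl)
}

snp_maf <- function(G) {
  p <- colMeans(G, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Exhaustive pairwise MDR scan
#'
#' Evaluates every SNP pair: builds the pair's 3x3 complete-case contingency
#' table, labels cells high/low risk at the pair's case:control threshold and
#' scores the labelling by balanced accuracy. Pairs whose complete cases lack
#' either class are degenerate and dropped with a message.
#'
#' @param cohort A [cohort_data] with at least two SNPs.
#' @param maf_min Optional minor-allele-frequency filter; SNPs below it are
#'   excluded before pairing. Default 0 (off): no QC filtering is applied.
#' @return Data frame of class `mdr_pairs`, one row per pair in lexicographic
#'   (i, j) order with columns `snp_i`, `snp_j`, `statistic`,
#'   `n_cases_used`, `n_controls_used`.
#' @export
pairwise_scan <- function(cohort, maf_min = 0) {
  stopifnot(inherits(cohort, "cohort_data"))
  G <- cohort$genotypes
  keep_snps <- seq_len(ncol(G))
  if (maf_min > 0) {
    keep_snps <- which(snp_maf(G) >= maf_min)
    G <- G[, keep_snps, drop = FALSE]
  }
  if (ncol(G) < 2L) stop("need at least 2 SNPs to scan", call. = FALSE)

  ind <- make_indicators(G)
  tot_cc <- cross_counts(ind)
  n_tot <- pair_totals(ind)
  ycase <- as.double(cohort$phenotype == "case")
  ba <- scan_engine(ind, tot_cc, n_tot, ycase)

  n_case <- pair_totals(ind, ycase)
  n_ctrl <- n_tot - n_case
  if (length(n_case) == 1L) {
    n_case <- matrix(n_case, ncol(G), ncol(G))
    n_ctrl <- matrix(n_ctrl[1L], ncol(G), ncol(G))
  }

  ut <- upper.tri(ba)
  ii <- row(ba)[ut]; jj <- col(ba)[ut]
  ord <- order(ii, jj)
  ii <- ii[ord]; jj <- jj[ord]
  out <- data.frame(snp_i = cohort$snps$snp_id[keep_snps][ii],
                    snp_j = cohort$snps$snp_id[keep_snps][jj],
                    statistic = ba[ut][ord],
                    n_cases_used = as.integer(n_case[ut][ord]),
                    n_controls_used = as.integer(n_ctrl[ut][ord]),
                    stringsAsFactors = FALSE)
  bad <- !is.finite(out$statistic)
  if (any(bad)) {
    message(sum(bad), " degenerate pair(s) dropped (no usable cases or controls)")
    out <- out[!bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("mdr_pairs", class(out))
  out
}

#' Best pairwise statistic per SNP
#'
#' For each SNP, the maximum balanced accuracy over all pairs containing it;
#' ties are broken by the lexicographically smallest partner id.
#'
#' @param results An `mdr_pairs` data frame from [pairwise_scan()].
#' @return Data frame with columns `snp_id`, `statistic`, `partner`.
#' @export
best_per_snp <- function(results) {
  if (nrow(results) == 0L) stop("no pair results", call. = FALSE)
  long <- data.frame(snp_id = c(results$snp_i, results$snp_j),
                     partner = c(results$snp_j, results$snp_i),
                     statistic = rep(results$statistic, 2L),
                     stringsAsFactors = FALSE)
  long <- long[order(long$snp_id, -long$statistic, long$partner), ]
  best <- long[!duplicated(long$snp_id), c("snp_id", "statistic", "partner")]
  rownames(best) <- NULL
  best
}
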