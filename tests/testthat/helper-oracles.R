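# Independent reference implementations used to cross-check the package.

# Brute-force balanced accuracy: labels each multilocus genotype cell by
# explicit counting, classifies every sample individually and reads
# sensitivity/specificity off the confusion matrix.
oracle_ba <- function(g_i, g_j, phenotype) {
  keep <- !is.na(g_i) & !is.na(g_j)
  g_i <- g_i[keep]; g_j <- g_j[keep]; ph <- phenotype[keep]
  n_case <- sum(ph == "case"); n_ctrl <- sum(ph == "control")
  if (n_case == 0L || n_ctrl == 0L) return(NA_real_)
  lab <- matrix("empty", 3L, 3L)
  for (a in 0:2) for (b in 0:2) {
    in_cell <- g_i == a & g_j == b
    ca <- sum(in_cell & ph == "case"); co <- sum(in_cell & ph == "control")
    if (ca + co > 0L)
      lab[a + 1L, b + 1L] <- if (ca * n_ctrl >= co * n_case) "high" else "low"
  }
  pred <- ifelse(lab[cbind(g_i + 1L, g_j + 1L)] == "high", "case", "control")
  tp <- sum(pred == "case" & ph == "case")
  tn <- sum(pred == "control" & ph == "control")
  0.5 * (tp / n_case + tn / n_ctrl)
}

# Exhaustive hypergeometric tail: enumerate every 2x2 table with the observed
# margins via exact binomial coefficients and normalise by their sum.
oracle_fisher_right <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  k <- max(0L, r1 - (n - c1)):min(r1, c1)
  w <- choose(c1, k) * choose(n - c1, r1 - k)
  sum(w[k >= a]) / sum(w)
}

# Small random cohort with optional missingness; both classes guaranteed.
random_cohort <- function(n, m, miss_rate = 0.1) {
  G <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  if (miss_rate > 0)
    G[matrix(runif(n * m) < miss_rate, n, m)] <- NA_integer_
  ph <- sample(c("case", "control"), n, replace = TRUE)
  ph[1:2] <- c("case", "control")
  cohort_data(G, ph, cohort_id = "random")
}

# Random non-degenerate pair contingency table.
random_contingency <- function(n = 40L) {
  repeat {
    g1 <- sample(0:2, n, replace = TRUE)
    g2 <- sample(0:2, n, replace = TRUE)
    ph <- sample(c("case", "control"), n, replace = TRUE)
    if (any(ph == "case") && any(ph == "control"))
      return(build_contingency(g1, g2, ph))
  }
}
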