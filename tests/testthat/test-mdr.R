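test_that("contingency tables count complete cases exactly", {
  tab <- build_contingency(c(0, 0, 1, 1), c(0, 0, 2, 2),
                           c("case", "control", "case", "case"))
  expect_equal(unname(tab$cases[1, 1]), 1L)
  expect_equal(unname(tab$controls[1, 1]), 1L)
  expect_equal(unname(tab$cases[2, 3]), 2L)
  expect_equal(tab$n_cases_used, 3L)
  expect_equal(tab$n_controls_used, 1L)
  expect_equal(sum(tab$cases) + sum(tab$controls), 4L)

  # a missing genotype drops the sample from this pair only
  tab2 <- build_contingency(c(NA, 0, 1, 1), c(0, 0, 2, 2),
                            c("case", "control", "case", "case"))
  expect_equal(tab2$n_cases_used, 2L)
  expect_error(build_contingency(c(NA, NA), c(0, 1), c("case", "control")),
               "degenerate")
})

test_that("permuting phenotype conserves per-cell totals", {
  set.seed(8)
  g1 <- sample(0:2, 60, TRUE); g2 <- sample(0:2, 60, TRUE)
  ph <- sample(c("case", "control"), 60, TRUE)
  a <- build_contingency(g1, g2, ph)
  b <- build_contingency(g1, g2, permute_phenotype(ph))
  expect_identical(a$cases + a$controls, b$cases + b$controls)
  expect_equal(b$n_cases_used, a$n_cases_used)
})

test_that("cell labelling follows the threshold with ties going high", {
  g1 <- c(0, 0, 0, 0, 1, 1); g2 <- c(0, 0, 0, 0, 0, 0)
  ph <- c("case", "case", "case", "control", "case", "control")
  tab <- build_contingency(g1, g2, ph)  # 4 cases, 2 controls
  lab <- label_cells(tab, threshold = 1)
  expect_equal(unname(lab[1, 1]), "high")   # 3 cases vs 1 control
  expect_equal(unname(lab[2, 1]), "high")   # 1:1 tie -> high
  expect_equal(unname(lab[3, 3]), "empty")
  # at the default cohort-ratio threshold (2), the tie cell flips low
  expect_equal(unname(label_cells(tab)[2, 1]), "low")
  expect_error(label_cells(tab, threshold = -1), "> 0")
})

test_that("balanced accuracy matches hand-worked examples", {
  # perfect separation
  tab <- build_contingency(c(0, 0, 1, 1), c(0, 0, 1, 1),
                           c("case", "case", "control", "control"))
  expect_equal(balanced_accuracy(tab), 1.0)

  # constant-high labelling: sensitivity 1, specificity 0
  lab <- matrix("high", 3, 3)
  expect_equal(balanced_accuracy(tab, lab), 0.5)

  # cells (0,0)=(10,5), (0,1)=(2,8): BA = (10/12 + 8/13) / 2
  g1 <- rep(0, 25)
  g2 <- rep(c(0, 1), c(15, 10))
  ph <- c(rep(c("case", "control"), c(10, 5)), rep(c("case", "control"), c(2, 8)))
  tab2 <- build_contingency(g1, g2, ph)
  lab2 <- label_cells(tab2, threshold = 1)
  expect_equal(unname(lab2[1, 1:2]), c("high", "low"))
  expect_equal(balanced_accuracy(tab2, lab2), (10 / 12 + 8 / 13) / 2)
  expect_equal(oracle_ba(g1, g2, ph), 0.5 * (10 / 12 + 8 / 13),
               tolerance = 1e-12)
})

test_that("vectorised scan equals the per-sample brute-force oracle", {
  set.seed(42)
  for (rep in 1:50) {
    co <- random_cohort(n = sample(10:50, 1), m = sample(2:6, 1))
    pairs <- suppressMessages(pairwise_scan(co))
    for (r in seq_len(nrow(pairs))) {
      i <- match(pairs$snp_i[r], co$snps$snp_id)
      j <- match(pairs$snp_j[r], co$snps$snp_id)
      expect_identical(pairs$statistic[r],
                       oracle_ba(co$genotypes[, i], co$genotypes[, j],
                                 co$phenotype))
    }
  }
})

test_that("scan returns C(m,2) ordered pairs and mdr_pair agrees", {
  set.seed(7)
  co <- random_cohort(20, 4, miss_rate = 0)
  pairs <- pairwise_scan(co)
  expect_equal(nrow(pairs), choose(4, 2))
  expect_true(all(pairs$snp_i < pairs$snp_j))
  expect_identical(pairs, pairwise_scan(co))  # deterministic
  for (r in seq_len(nrow(pairs))) {
    mp <- mdr_pair(co, pairs$snp_i[r], pairs$snp_j[r])
    expect_identical(mp$statistic, pairs$statistic[r])
  }
  expect_error(pairwise_scan(cohort_data(co$genotypes[, 1, drop = FALSE],
                                         co$phenotype)), "2 SNPs")
})

test_that("monomorphic SNPs are still evaluated, not special-cased", {
  set.seed(9)
  G <- cbind(mono = rep(0L, 30), poly = sample(0:2, 30, TRUE),
             poly2 = sample(0:2, 30, TRUE))
  co <- cohort_data(G, rep(c("case", "control"), 15))
  pairs <- pairwise_scan(co)
  expect_equal(nrow(pairs), 3L)
  expect_true(all(is.finite(pairs$statistic)))
})

test_that("labels and statistic are invariant to replicating every sample", {
  set.seed(13)
  g1 <- sample(0:2, 40, TRUE); g2 <- sample(0:2, 40, TRUE)
  ph <- sample(c("case", "control"), 40, TRUE)
  ph[1:2] <- c("case", "control")
  t1 <- build_contingency(g1, g2, ph)
  t3 <- build_contingency(rep(g1, 3), rep(g2, 3), rep(ph, 3))
  expect_identical(t3$cases, t1$cases * 3L)
  expect_identical(label_cells(t3), label_cells(t1))
  expect_equal(balanced_accuracy(t3), balanced_accuracy(t1))
})

test_that("MDR labelling maximises balanced accuracy over labellings", {
  set.seed(17)
  for (rep in 1:200) {
    tab <- random_contingency(40)
    lab <- label_cells(tab)
    ba <- balanced_accuracy(tab, lab)
    # complement labelling scores 1 - BA, so BA >= 0.5 always
    comp <- ifelse(lab == "high", "low", ifelse(lab == "low", "high", "empty"))
    expect_equal(balanced_accuracy(tab, comp), 1 - ba)
    expect_gte(ba, 0.5)
    expect_gte(ba, balanced_accuracy(tab, comp))
    # random labellings never beat the MDR labelling
    rnd <- matrix(sample(c("high", "low"), 9, TRUE), 3, 3)
    rnd[lab == "empty"] <- "empty"
    expect_gte(ba + 1e-12, balanced_accuracy(tab, rnd))
  }
})

test_that("null pairs overfit above 0.5, motivating the permutation test", {
  set.seed(19)
  stats <- replicate(1000, balanced_accuracy(random_contingency(30)))
  expect_gt(mean(stats), 0.5)
})

test_that("best_per_snp takes the max with partner-id tie-breaks", {
  pairs <- data.frame(snp_i = c("a", "a", "b"), snp_j = c("b", "c", "c"),
                      statistic = c(0.61, 0.52, 0.55),
                      stringsAsFactors = FALSE)
  best <- best_per_snp(pairs)
  expect_equal(best$statistic[best$snp_id == "a"], 0.61)
  expect_equal(best$partner[best$snp_id == "a"], "b")
  # tie at the max: smaller partner id wins
  tied <- data.frame(snp_i = c("a", "a"), snp_j = c("c", "b"),
                     statistic = c(0.6, 0.6), stringsAsFactors = FALSE)
  expect_equal(best_per_snp(tied)$partner[1], "b")
})

test_that("planted epistatic pair tops the scan in a synthetic cohort", {
  sim <- simulate_cohort(sim_config(n_cases = 500, n_controls = 500,
                                    n_snps = 100, seed = 23))
  pairs <- pairwise_scan(sim$cohort)
  top <- pairs[which.max(pairs$statistic), ]
  expect_setequal(c(top$snp_i, top$snp_j), sim$truth$planted_ids)
})
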