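toy_snps <- function() {
  data.frame(snp_id = c("s1", "s2", "s3", "s4"),
             chrom = c("1", "1", "1", "2"),
             pos = c(500000L, 499999L, 1025000L, 500000L),
             stringsAsFactors = FALSE)
}

toy_genes <- function() {
  data.frame(gene_id = c("GA", "GB"), chrom = c("1", "2"),
             start = c(1000000L, 2000000L), stop = c(1050000L, 2100000L),
             stringsAsFactors = FALSE)
}

test_that("window mapping is inclusive at exactly the window distance", {
  map <- map_snps_to_genes(toy_snps(), toy_genes(), window = 500000)
  assigned <- map$pairs
  # s1 sits exactly 500 kb from GA's start: assigned
  expect_true(any(assigned$snp_id == "s1" & assigned$gene_id == "GA"))
  # s2 is one bp further: not assigned
  expect_false("s2" %in% assigned$snp_id)
  # s3 lies inside GA; s4 is on another chromosome, 1.5 Mb from GB
  expect_true(any(assigned$snp_id == "s3" & assigned$gene_id == "GA"))
  expect_false("s4" %in% assigned$snp_id)
})

test_that("SNPs map to every gene whose window covers them", {
  genes <- data.frame(gene_id = c("X", "Y"), chrom = c("chr1", "1"),
                      start = c(100L, 150L), stop = c(300L, 400L),
                      stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = "s", chrom = "1", pos = 200L,
                     stringsAsFactors = FALSE)
  map <- map_snps_to_genes(snps, genes, window = 0)
  # 'chr' prefixes are normalised; overlapping genes both receive the SNP
  expect_setequal(map$pairs$gene_id, c("X", "Y"))
  expect_error(map_snps_to_genes(snps, genes, window = -1), ">= 0")
})

test_that("right-tailed Fisher matches enumeration and stats::fisher.test", {
  expect_equal(fisher_right_tail(3, 1, 1, 3), 17 / 70, tolerance = 1e-12)
  expect_equal(fisher_right_tail(4, 0, 0, 4), 1 / 70, tolerance = 1e-12)
  # minimum of the support: the whole tail
  expect_equal(fisher_right_tail(0, 4, 4, 0), 1.0)

  set.seed(2)
  for (rep in 1:100) {
    tab <- as.integer(rmultinom(1, sample(4:40, 1), runif(4, 0.05, 1)))
    p <- fisher_right_tail(tab[1], tab[2], tab[3], tab[4])
    expect_equal(p, oracle_fisher_right(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-10)
    ft <- stats::fisher.test(matrix(tab, 2, byrow = TRUE),
                             alternative = "greater")
    expect_equal(p, ft$p.value, tolerance = 1e-7)
  }
  expect_error(fisher_right_tail(-1, 0, 0, 1), "non-negative")
  expect_error(fisher_right_tail(0, 0, 0, 0), "at least one")
})

test_that("gene enrichment builds the documented 2x2 and conserves margins", {
  snps <- data.frame(snp_id = sprintf("s%02d", 1:20), chrom = "1",
                     pos = as.integer(seq(1e6, by = 1e6, length.out = 20)),
                     stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("G1", "G2"), chrom = "1",
                      start = c(1000000L, 5000000L),
                      stop = c(2000000L, 6000000L), stringsAsFactors = FALSE)
  map <- map_snps_to_genes(snps, genes, window = 0)
  pv <- stats::setNames(rep(1, 20), snps$snp_id)
  pv[c("s01", "s02", "s10")] <- 0.01
  res <- gene_enrichment(map, pv, alpha = 0.05)
  g1 <- res[res$entity_id == "G1", ]
  expect_equal(unlist(g1[, c("a", "b", "c", "d")], use.names = FALSE),
               c(2, 0, 1, 17))
  expect_equal(g1$p_value, fisher_right_tail(2, 0, 1, 17))
  # margin conservation: a + c = total significant, a + b = mapped SNPs
  expect_true(all(res$a + res$c == 3))
  expect_true(all(res$a + res$b == c(2, 2)))
  expect_true(all(res$a + res$b + res$c + res$d == 20))

  # alpha = 1 makes every SNP significant and every gene p = 1
  res1 <- gene_enrichment(map, pv, alpha = 1)
  expect_true(all(res1$p_value == 1))

  # a gene with no mapped SNP is flagged with p = 1
  far <- rbind(genes, data.frame(gene_id = "G0", chrom = "9",
                                 start = 1L, stop = 2L))
  res0 <- gene_enrichment(map_snps_to_genes(snps, far, window = 0), pv)
  expect_true(res0$flagged[res0$entity_id == "G0"])
  expect_equal(res0$p_value[res0$entity_id == "G0"], 1)

  expect_error(gene_enrichment(map, pv[-1]), "without a p-value")
})

test_that("adding a significant SNP to a gene never increases its p-value", {
  set.seed(6)
  snps <- data.frame(snp_id = sprintf("s%02d", 1:30), chrom = "1",
                     pos = as.integer(seq(1e6, by = 1e6, length.out = 30)),
                     stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = "G", chrom = "1", start = 1000000L,
                      stop = 10000000L, stringsAsFactors = FALSE)
  map <- map_snps_to_genes(snps, genes, window = 0)
  inside <- map$pairs$snp_id
  pv <- stats::setNames(runif(30, 0.2, 1), snps$snp_id)
  p_prev <- gene_enrichment(map, pv)$p_value
  for (s in inside) {
    pv[s] <- 0.01
    p_now <- gene_enrichment(map, pv)$p_value
    expect_lte(p_now, p_prev + 1e-15)
    p_prev <- p_now
  }
})

test_that("gene-level test is conservative under random significance labels", {
  set.seed(14)
  snps <- data.frame(snp_id = sprintf("s%03d", 1:400), chrom = "1",
                     pos = as.integer(seq(1e6, by = 5e5, length.out = 400)),
                     stringsAsFactors = FALSE)
  starts <- as.integer(seq(2e6, by = 1e7, length.out = 20))
  genes <- data.frame(gene_id = sprintf("G%02d", 1:20), chrom = "1",
                      start = starts, stop = starts + 4000000L,
                      stringsAsFactors = FALSE)
  map <- map_snps_to_genes(snps, genes, window = 0)
  frac <- replicate(40, {
    pv <- stats::setNames(ifelse(runif(400) < 0.05, 0.01, 0.99), snps$snp_id)
    mean(gene_enrichment(map, pv)$p_value <= 0.05)
  })
  expect_lte(mean(frac), 0.05 + 0.02)
})

test_that("set enrichment unwinds to the documented Fisher table", {
  gene_p <- stats::setNames(rep(1, 20), sprintf("g%02d", 1:20))
  gene_p[c("g01", "g02", "g03", "g11", "g12")] <- 0.01
  sets <- list(S = sprintf("g%02d", 1:5))
  res <- set_enrichment(sets, gene_p, alpha = 0.05)
  # 3 of 5 members significant, 2 of 15 outside
  expect_equal(unlist(res[, c("a", "b", "c", "d")], use.names = FALSE),
               c(3, 2, 2, 13))
  expect_equal(res$p_value, fisher_right_tail(3, 2, 2, 13))

  # members outside the universe are dropped with a message
  sets2 <- list(S = c("g01", "nosuchgene"))
  expect_message(res2 <- set_enrichment(sets2, gene_p), "outside")
  expect_equal(res2$a + res2$b, 1)

  # no significant genes: every set gets p = 1
  res3 <- set_enrichment(sets, stats::setNames(rep(1, 20), names(gene_p)))
  expect_true(all(res3$p_value == 1))

  # empty-in-universe set is flagged
  expect_message(res4 <- set_enrichment(list(S = "zzz"), gene_p), "outside")
  expect_true(res4$flagged)
  expect_equal(res4$p_value, 1)
})

test_that("replication keeps entities significant in both cohorts", {
  det <- data.frame(entity_id = c("GO:0016831", "S2", "S3"),
                    p_value = c(0.023, 0.03, 1), stringsAsFactors = FALSE)
  rep_ <- data.frame(entity_id = c("GO:0016831", "S2", "S3"),
                     p_value = c(0.043, 0.06, 0.01), stringsAsFactors = FALSE)
  out <- replicate_enrichment(det, rep_, alpha = 0.05)
  expect_equal(out$entity_id, "GO:0016831")
  expect_equal(out$p_detect, 0.023)
  expect_equal(out$p_replicate, 0.043)

  none <- replicate_enrichment(det, transform(rep_, p_value = 1))
  expect_equal(nrow(none), 0L)

  lvl_gene <- structure(det, level = "gene")
  lvl_set <- structure(rep_, level = "set")
  expect_error(replicate_enrichment(lvl_gene, lvl_set), "different levels")
})
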