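#' Map SNPs to genes by a symmetric window
#'
#' A SNP is assigned to a gene when it lies on the same chromosome within
#' `window` bp of the gene body: `start - window <= pos <= stop + window`,
#' boundaries inclusive. A SNP may map to several genes; SNPs mapping to no
#' gene remain unassigned (they still count in the enrichment background).
#' Chromosome labels are compared after stripping an optional `chr` prefix.
#' Overlap is computed with `GenomicRanges::findOverlaps`.
#'
#' @param snps SNP map data frame (`snp_id`, `chrom`, `pos`).
#' @param genes Gene regions data frame (`gene_id`, `chrom`, `start`, `stop`,
#'   1-based inclusive), e.g. from [read_bed_genes()].
#' @param window Flanking window in bp; default 500000 (500 kb) on each side,
#'   strand-agnostic.
#' @return Object of class `snp_gene_map`: list with `pairs` (data frame
#'   `snp_id`, `gene_id`), `snp_ids`, `gene_ids` and `window`.
#' @export
map_snps_to_genes <- function(snps, genes, window = 500000L) {
  if (window < 0) stop("window must be >= 0", call. = FALSE)
  snps <- validate_snp_map(snps)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (any(genes$start > genes$stop))
    stop("gene start must be <= stop", call. = FALSE)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in annotation", call. = FALSE)

  if (nrow(genes) == 0L || nrow(snps) == 0L) {
    pairs <- data.frame(snp_id = character(), gene_id = character(),
                        stringsAsFactors = FALSE)
  } else {
    lev <- unique(c(norm_chrom(snps$chrom), norm_chrom(genes$chrom)))
    gr_snp <- GenomicRanges::GRanges(
      factor(norm_chrom(snps$chrom), levels = lev),
      IRanges::IRanges(snps$pos, snps$pos))
    gr_gene <- GenomicRanges::GRanges(
      factor(norm_chrom(genes$chrom), levels = lev),
      IRanges::IRanges(pmax(1L, genes$start - as.integer(window)),
                       genes$stop + as.integer(window)))
    hits <- GenomicRanges::findOverlaps(gr_snp, gr_gene)
    pairs <- data.frame(
      snp_id = snps$snp_id[S4Vectors::queryHits(hits)],
      gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
      stringsAsFactors = FALSE)
    pairs <- pairs[order(pairs$gene_id, pairs$snp_id), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  structure(list(pairs = pairs, snp_ids = snps$snp_id,
                 gene_ids = genes$gene_id, window = as.integer(window)),
            class = "snp_gene_map")
}

#' @export
print.snp_gene_map <- function(x, ...) {
  cat(sprintf("<snp_gene_map>  %d SNPs, %d genes, window %d bp\n",
              length(x$snp_ids), length(x$gene_ids), x$window))
  cat(sprintf("  %d assignments; %d SNPs unassigned\n", nrow(x$pairs),
              length(setdiff(x$snp_ids, x$pairs$snp_id))))
  invisible(x)
}

#' Right-tailed Fisher's exact test for a 2x2 table
#'
#' Probability, under fixed margins, of a table whose first cell is at least
#' `a`: the upper tail of the hypergeometric distribution, summed on the
#' log-gamma scale (`lchoose`) for numerical stability. Relative error is
#' below 1e-10 across the support.
#'
#' @param a,b,c,d Non-negative counts: `a` significant items inside the
#'   entity, `b` non-significant inside, `c` significant outside, `d`
#'   non-significant outside.
#' @return The right-tail p-value in (0, 1].
#' @examples
#' fisher_right_tail(3, 1, 1, 3)  # 17/70
#' @export
fisher_right_tail <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  n <- a + b + c + d
  if (n < 1) stop("table must hold at least one item", call. = FALSE)
  r1 <- a + b   # items inside the entity
  c1 <- a + c   # significant items
  kmax <- min(r1, c1)
  if (a > kmax) return(0)   # unreachable for a consistent table
  k <- seq.int(a, kmax)
  p <- sum(exp(lchoose(c1, k) + lchoose(n - c1, r1 - k) - lchoose(n, r1)))
  min(p, 1)
}

new_enrichment_result <- function(entity_id, a, b, c, d, p_value, flagged,
                                  level, alpha) {
  out <- data.frame(entity_id = entity_id, a = a, b = b, c = c, d = d,
                    p_value = p_value, flagged = flagged,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$entity_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "level") <- level
  attr(out, "alpha") <- alpha
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Gene-level overabundance test
#'
#' For each gene, tests whether its mapped SNPs hold more significant SNPs
#' (p <= `alpha`) than expected from the genome-wide rate, by a right-tailed
#' Fisher's exact test. The universe is every SNP with a p-value; SNPs mapped
#' to no gene stay in the "outside" counts, and a SNP mapped to several genes
#' is "inside" for each of them while contributing once to the universe.
#' Region size enters through the number of mapped SNPs.
#'
#' @param map A [map_snps_to_genes()] result.
#' @param snp_pvalues Named numeric vector of per-SNP p-values (names are
#'   snp_ids), or the `snps` data frame from [mdr_scan()].
#' @param alpha SNP-level significance dichotomy (default 0.05).
#' @return Data frame of class `enrichment_result`, one row per gene, sorted
#'   by ascending p-value: `entity_id`, the 2x2 counts `a`, `b`, `c`, `d`,
#'   `p_value` and `flagged` (TRUE for genes with no mapped SNP, which get
#'   p = 1).
#' @export
gene_enrichment <- function(map, snp_pvalues, alpha = 0.05) {
  stopifnot(inherits(map, "snp_gene_map"))
  snp_pvalues <- as_named_pvalues(snp_pvalues, "snp_id")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]", call. = FALSE)
  unmatched <- setdiff(unique(map$pairs$snp_id), names(snp_pvalues))
  if (length(unmatched))
    stop("mapped SNP(s) without a p-value: ",
         paste(utils::head(unmatched, 3L), collapse = ", "), call. = FALSE)

  sig <- snp_pvalues <= alpha
  n_sig <- sum(sig); n_all <- length(sig)
  res <- lapply(map$gene_ids, function(g) {
    ms <- map$pairs$snp_id[map$pairs$gene_id == g]
    a <- sum(sig[ms]); b <- length(ms) - a
    c_ <- n_sig - a; d <- (n_all - length(ms)) - c_
    list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c_), d = as.numeric(d),
         p = if (length(ms)) fisher_right_tail(a, b, c_, d) else 1,
         flagged = length(ms) == 0L)
  })
  new_enrichment_result(map$gene_ids,
                        vapply(res, `[[`, 1, "a"), vapply(res, `[[`, 1, "b"),
                        vapply(res, `[[`, 1, "c"), vapply(res, `[[`, 1, "d"),
                        vapply(res, `[[`, 1, "p"),
                        vapply(res, `[[`, TRUE, "flagged"),
                        level = "gene", alpha = alpha)
}

#' Gene-set overabundance test
#'
#' For each set, tests whether member genes are enriched for significant
#' genes (p <= `alpha`) relative to the gene universe, by a right-tailed
#' Fisher's exact test. The universe is every gene with a gene-level p-value;
#' set members outside the universe are dropped with a message, and a set
#' with no member in the universe gets p = 1 and is flagged.
#'
#' @param sets Named list of member-gene vectors (see [read_gmt()]).
#' @param gene_pvalues Named numeric vector of gene-level p-values, or an
#'   `enrichment_result` at gene level.
#' @param alpha Gene-level significance dichotomy (default 0.05).
#' @return Data frame of class `enrichment_result`, one row per set.
#' @export
set_enrichment <- function(sets, gene_pvalues, alpha = 0.05) {
  gene_pvalues <- as_named_pvalues(gene_pvalues, "entity_id")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]", call. = FALSE)
  universe <- names(gene_pvalues)
  sig <- gene_pvalues <= alpha
  n_sig <- sum(sig); n_all <- length(sig)
  dropped <- sum(vapply(sets, function(m) length(setdiff(m, universe)), 1L))
  if (dropped > 0L)
    message(dropped, " set member(s) outside the gene universe dropped")
  res <- lapply(sets, function(members) {
    m <- intersect(members, universe)
    a <- sum(sig[m]); b <- length(m) - a
    c_ <- n_sig - a; d <- (n_all - length(m)) - c_
    list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c_), d = as.numeric(d),
         p = if (length(m)) fisher_right_tail(a, b, c_, d) else 1,
         flagged = length(m) == 0L)
  })
  new_enrichment_result(names(sets),
                        vapply(res, `[[`, 1, "a"), vapply(res, `[[`, 1, "b"),
                        vapply(res, `[[`, 1, "c"), vapply(res, `[[`, 1, "d"),
                        vapply(res, `[[`, 1, "p"),
                        vapply(res, `[[`, TRUE, "flagged"),
                        level = "set", alpha = alpha)
}

as_named_pvalues <- function(x, id_col) {
  if (is.data.frame(x)) {
    pcol <- if ("p_value" %in% names(x)) "p_value" else
      stop("data frame must carry a p_value column", call. = FALSE)
    idc <- intersect(c(id_col, "snp_id", "entity_id", "gene_id"), names(x))[1L]
    if (is.na(idc)) stop("cannot find an identifier column", call. = FALSE)
    stats::setNames(x[[pcol]], x[[idc]])
  } else {
    if (is.null(names(x))) stop("p-values must be named", call. = FALSE)
    x
  }
}

#' @export
print.enrichment_result <- function(x, n = 10L, ...) {
  cat(sprintf("<enrichment_result level='%s' alpha=%.3g>  %d entities, %d with p <= alpha\n",
              attr(x, "level"), attr(x, "alpha"), nrow(x),
              sum(x$p_value <= attr(x, "alpha"))))
  print.data.frame(utils::head(x, n), row.names = FALSE)
  invisible(x)
}

#' Two-cohort replication filter
#'
#' Keeps the entities significant at `alpha` in BOTH the detection and the
#' replication analyses, sorted by the worse of the two p-values.
#'
#' @param detection,replication `enrichment_result` data frames at the same
#'   level (gene or set).
#' @param alpha Replication significance level (default 0.05).
#' @return Data frame with columns `entity_id`, `p_detect`, `p_replicate`,
#'   sorted by `pmax(p_detect, p_replicate)` ascending.
#' @export
replicate_enrichment <- function(detection, replication, alpha = 0.05) {
  lv_d <- attr(detection, "level"); lv_r <- attr(replication, "level")
  if (!is.null(lv_d) && !is.null(lv_r) && !identical(lv_d, lv_r))
    stop("detection and replication results are at different levels (",
         lv_d, " vs ", lv_r, ")", call. = FALSE)
  common <- intersect(detection$entity_id, replication$entity_id)
  pd <- stats::setNames(detection$p_value, detection$entity_id)[common]
  pr <- stats::setNames(replication$p_value, replication$entity_id)[common]
  keep <- pd <= alpha & pr <= alpha
  out <- data.frame(entity_id = common[keep],
                    p_detect = unname(pd[keep]),
                    p_replicate = unname(pr[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(pmax(out$p_detect, out$p_replicate), out$entity_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
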