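#' Simulation configuration
#'
#' Describes a synthetic paired case-control GWAS: cohort sizes, SNP panel,
#' planted epistatic pairs and the gene/gene-set annotation layout. The
#' defaults are the desk-scale study conditions used throughout the package's
#' validation: a single planted checkerboard pair (effect 0.3, MAF 0.3,
#' prevalence 0.5), balanced cohorts, one chromosome per gene with SNPs on a
#' 400 kb grid so a 500 kb mapping window assigns a handful of SNPs per gene.
#'
#' @param n_cases,n_controls Detection-cohort sample quotas.
#' @param n_snps Number of SNPs on the shared panel.
#' @param maf_range Range for background minor-allele frequencies (drawn
#'   uniformly per SNP), within (0, 0.5].
#' @param n_planted_pairs Number of planted epistatic SNP pairs (0 or more).
#' @param effect,prevalence,planted_maf Parameters of the planted
#'   [xor_model()] pairs.
#' @param n_genes,n_sets Number of gene regions / gene sets in the annotation.
#' @param n_chrom Number of synthetic chromosomes; default one per gene.
#' @param spacing SNP grid spacing in bp.
#' @param gene_length Gene length in bp.
#' @param ld_rho Optional block-LD parameter in \[0, 1): each background
#'   genotype is copied from the adjacent SNP (same chromosome) with this
#'   probability, giving a simple decaying correlation structure. 0 disables.
#' @param replication_fraction Replication cohort size as a fraction of the
#'   detection cohort.
#' @param max_draws Rejection-sampling budget for phenotype assignment;
#'   default `200 * (n_cases + n_controls)`.
#' @param seed Integer seed; the entire simulation output is a pure function
#'   of this configuration.
#' @return An object of class `sim_config` (a validated list). The element
#'   `planted` holds, per planted pair, the penetrance model, the SNP panel
#'   indices, the designated gene ids and the designated set id.
#' @export
sim_config <- function(n_cases = 500L, n_controls = 500L, n_snps = 100L,
                       maf_range = c(0.05, 0.5),
                       n_planted_pairs = 1L, effect = 0.3, prevalence = 0.5,
                       planted_maf = 0.3,
                       n_genes = 10L, n_sets = 4L, n_chrom = NULL,
                       spacing = 400000L, gene_length = 50000L,
                       ld_rho = 0, replication_fraction = 0.5,
                       max_draws = NULL, seed = 1L) {
  n_cases <- as.integer(n_cases); n_controls <- as.integer(n_controls)
  n_snps <- as.integer(n_snps); n_genes <- as.integer(n_genes)
  n_sets <- as.integer(n_sets); n_planted_pairs <- as.integer(n_planted_pairs)
  if (n_cases < 1L || n_controls < 1L)
    stop("n_cases and n_controls must be >= 1", call. = FALSE)
  if (n_snps < 1L) stop("n_snps must be >= 1", call. = FALSE)
  if (length(maf_range) != 2L || maf_range[1L] <= 0 || maf_range[2L] > 0.5 ||
      maf_range[1L] > maf_range[2L])
    stop("maf_range must be an interval within (0, 0.5]", call. = FALSE)
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)", call. = FALSE)
  if (n_genes < 1L || n_genes > n_snps)
    stop("need 1 <= n_genes <= n_snps (each gene must cover a SNP)", call. = FALSE)
  if (is.null(n_chrom)) n_chrom <- n_genes
  n_chrom <- as.integer(n_chrom)
  if (n_chrom < 1L || n_chrom > n_snps)
    stop("need 1 <= n_chrom <= n_snps", call. = FALSE)
  if (is.null(max_draws)) max_draws <- 200L * (n_cases + n_controls)

  planted <- list()
  if (n_planted_pairs > 0L) {
    model <- xor_model(prevalence, effect, planted_maf)
    if (2L * n_planted_pairs > n_genes)
      stop("need n_genes >= 2 * n_planted_pairs", call. = FALSE)
    per_chrom <- ceiling(n_snps / n_chrom)
    centre <- function(k) min((k - 1L) * per_chrom + ceiling(per_chrom / 2), n_snps)
    anchors <- vapply(seq_len(min(2L * n_planted_pairs, n_chrom)), centre, 1)
    # if fewer chromosomes than planted SNPs, fall back to interior grid
    # points so every planted SNP keeps a full mapping window around it
    if (length(anchors) < 2L * n_planted_pairs || anyDuplicated(anchors)) {
      pts <- round(seq(1L, n_snps, length.out = 2L * n_planted_pairs + 2L))
      anchors <- unique(as.integer(pts[seq(2L, length(pts) - 1L)]))
    }
    if (length(anchors) < 2L * n_planted_pairs)
      stop("too few SNPs to place the planted pairs", call. = FALSE)
    for (k in seq_len(n_planted_pairs)) {
      idx <- as.integer(anchors[c(2L * k - 1L, 2L * k)])
      planted[[k]] <- list(model = model, snp_idx = idx,
                           gene_ids = sprintf("G%02d", c(2L * k - 1L, 2L * k)),
                           set_id = "S1")
    }
  }
  if (n_sets < 1L + (n_planted_pairs > 0L))
    stop("n_sets too small", call. = FALSE)

  structure(list(n_cases = n_cases, n_controls = n_controls, n_snps = n_snps,
                 maf_range = maf_range, planted = planted,
                 n_genes = n_genes, n_sets = n_sets, n_chrom = n_chrom,
                 spacing = as.integer(spacing),
                 gene_length = as.integer(gene_length),
                 ld_rho = ld_rho,
                 replication_fraction = replication_fraction,
                 max_draws = as.integer(max_draws),
                 seed = as.integer(seed)),
            class = "sim_config")
}

planted_snp_idx <- function(config)
  unlist(lapply(config$planted, `[[`, "snp_idx"), use.names = FALSE)

# Deterministic SNP panel layout: SNPs are split into contiguous blocks, one
# per chromosome, and placed on a uniform bp grid starting at 1e6.
panel_layout <- function(config) {
  per_chrom <- ceiling(config$n_snps / config$n_chrom)
  idx <- seq_len(config$n_snps)
  chrom_no <- (idx - 1L) %/% per_chrom + 1L
  within <- (idx - 1L) %% per_chrom
  data.frame(snp_id = sprintf("snp%04d", idx),
             chrom = as.character(chrom_no),
             pos = as.integer(1e6 + within * config$spacing),
             stringsAsFactors = FALSE)
}

# RNG draw order within one run: (1) background MAFs, (2) per cohort: planted
# rejection sampling batches (genotypes then disease), background genotype
# matrix column by column, LD copying masks.
draw_mafs <- function(config) {
  mafs <- stats::runif(config$n_snps, config$maf_range[1L], config$maf_range[2L])
  for (pl in config$planted) {
    mafs[pl$snp_idx[1L]] <- pl$model$maf_a
    mafs[pl$snp_idx[2L]] <- pl$model$maf_b
  }
  mafs
}

draw_cohort <- function(config, mafs, layout, n_cases, n_controls, cohort_id) {
  n <- n_cases + n_controls
  m <- config$n_snps
  planted_idx <- planted_snp_idx(config)
  n_pl <- length(planted_idx)

  G <- matrix(NA_integer_, n, m)
  if (n_pl > 0L) {
    # retrospective quota sampling: draw planted genotypes under HWE, assign
    # disease from the penetrance table(s), keep until both quotas are met
    acc_case <- matrix(NA_integer_, 0L, n_pl)
    acc_ctrl <- matrix(NA_integer_, 0L, n_pl)
    drawn <- 0L
    batch <- max(1000L, 2L * n)
    while ((nrow(acc_case) < n_cases || nrow(acc_ctrl) < n_controls)) {
      if (drawn >= config$max_draws)
        stop("rejection sampling exceeded the draw budget (", config$max_draws,
             "); increase effect feasibility, prevalence or max_draws",
             call. = FALSE)
      b <- min(batch, config$max_draws - drawn)
      drawn <- drawn + b
      gp <- vapply(planted_idx,
                   function(j) stats::rbinom(b, 2L, mafs[j]), integer(b))
      gp <- matrix(gp, nrow = b)
      p_healthy <- rep(1, b)
      col0 <- 0L
      for (pl in config$planted) {
        pen <- pl$model$table[cbind(gp[, col0 + 1L] + 1L, gp[, col0 + 2L] + 1L)]
        p_healthy <- p_healthy * (1 - pen)
        col0 <- col0 + 2L
      }
      disease <- stats::runif(b) < (1 - p_healthy)
      if (nrow(acc_case) < n_cases) {
        take <- which(disease)[seq_len(min(sum(disease), n_cases - nrow(acc_case)))]
        acc_case <- rbind(acc_case, gp[take, , drop = FALSE])
      }
      if (nrow(acc_ctrl) < n_controls) {
        take <- which(!disease)[seq_len(min(sum(!disease), n_controls - nrow(acc_ctrl)))]
        acc_ctrl <- rbind(acc_ctrl, gp[take, , drop = FALSE])
      }
    }
    G[, planted_idx] <- rbind(acc_case, acc_ctrl)
  }
  phenotype <- rep(c("case", "control"), c(n_cases, n_controls))

  bg <- setdiff(seq_len(m), planted_idx)
  for (j in bg) G[, j] <- stats::rbinom(n, 2L, mafs[j])

  if (config$ld_rho > 0) {
    chrom <- layout$chrom
    for (j in seq_len(m)[-1L]) {
      if (chrom[j] != chrom[j - 1L]) next
      if (j %in% planted_idx || (j - 1L) %in% planted_idx) next
      copy <- stats::runif(n) < config$ld_rho
      G[copy, j] <- G[copy, j - 1L]
    }
  }
  rownames(G) <- sprintf("%s_s%05d", cohort_id, seq_len(n))
  cohort_data(G, phenotype, layout, cohort_id)
}

#' Simulate a single case-control cohort
#'
#' Background SNP genotypes are independent Hardy-Weinberg draws with per-SNP
#' MAFs uniform over `maf_range` and are independent of the phenotype. For
#' planted pairs, genotypes are drawn under HWE and case/control status is
#' assigned by rejection sampling from the penetrance table until the
#' case/control quotas are met (retrospective ascertainment). Deterministic
#' given `config` (including its seed).
#'
#' @param config A [sim_config()].
#' @return List with elements `cohort` (a [cohort_data]) and `truth`
#'   (planted SNP indices/ids, models, designated genes and set, MAFs).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed, kind = "Mersenne-Twister")
  layout <- panel_layout(config)
  mafs <- draw_mafs(config)
  cohort <- draw_cohort(config, mafs, layout, config$n_cases,
                        config$n_controls, "detection")
  list(cohort = cohort, truth = sim_truth(config, layout, mafs))
}

sim_truth <- function(config, layout, mafs) {
  idx <- planted_snp_idx(config)
  list(planted_idx = idx,
       planted_ids = layout$snp_id[idx],
       pairs = lapply(config$planted, function(pl)
         list(snp_ids = layout$snp_id[pl$snp_idx], model = pl$model,
              gene_ids = pl$gene_ids, set_id = pl$set_id)),
       mafs = mafs)
}

#' Simulate gene annotation and gene sets for a SNP panel
#'
#' Tiles `n_genes` gene regions over the synthetic chromosomes so that every
#' gene covers at least one SNP. Genes designated for planted SNPs are
#' centred on those SNPs; remaining (decoy) genes are anchored, chromosome by
#' chromosome, on the SNP farthest from any gene already placed there.
#' Designated genes are members of their designated set; decoy genes are
#' partitioned over the remaining sets.
#'
#' @param config A [sim_config()].
#' @param snps SNP map data frame (as produced inside [simulate_cohort()]).
#' @return List with `genes` (data frame `gene_id`, `chrom`, `start`, `stop`),
#'   `sets` (named list as from [read_gmt()]) and `truth_set` (the designated
#'   set id, or `NULL` with no planted pairs).
#' @export
simulate_annotation <- function(config, snps) {
  stopifnot(inherits(config, "sim_config"))
  snps <- validate_snp_map(snps)
  planted_idx <- planted_snp_idx(config)
  half <- config$gene_length %/% 2L

  anchors <- integer(0)
  gene_ids <- character(0)
  for (pl in config$planted) {
    anchors <- c(anchors, pl$snp_idx)
    gene_ids <- c(gene_ids, pl$gene_ids)
  }
  n_decoy <- config$n_genes - length(anchors)
  decoy_ids <- setdiff(sprintf("G%02d", seq_len(config$n_genes)), gene_ids)

  chroms <- unique(snps$chrom)
  while (length(anchors) < config$n_genes) {
    # anchor on the emptiest chromosome, at the SNP farthest from any gene
    # already placed there (ties -> smallest index), for a deterministic spread
    counts <- vapply(chroms, function(ch) sum(snps$chrom[anchors] == ch), 1L)
    placed <- FALSE
    for (ci in order(counts, seq_along(chroms))) {
      cand <- setdiff(which(snps$chrom == chroms[ci]), anchors)
      if (!length(cand)) next
      here <- anchors[snps$chrom[anchors] == chroms[ci]]
      if (length(here)) {
        d <- vapply(cand, function(k) min(abs(snps$pos[k] - snps$pos[here])), 1)
        cand <- cand[order(-d, cand)]
      }
      anchors <- c(anchors, cand[1L])
      placed <- TRUE
      break
    }
    if (!placed)
      stop("annotation layout infeasible: too few SNPs to anchor every gene",
           call. = FALSE)
  }
  gene_ids <- c(gene_ids, decoy_ids[seq_len(n_decoy)])

  genes <- data.frame(gene_id = gene_ids,
                      chrom = snps$chrom[anchors],
                      start = pmax(1L, snps$pos[anchors] - half),
                      stop = snps$pos[anchors] + half,
                      stringsAsFactors = FALSE)
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL

  truth_genes <- unlist(lapply(config$planted, `[[`, "gene_ids"))
  truth_set <- if (length(config$planted)) config$planted[[1L]]$set_id else NULL
  sets <- list()
  if (!is.null(truth_set)) sets[[truth_set]] <- truth_genes
  decoys <- setdiff(genes$gene_id, truth_genes)
  n_decoy_sets <- config$n_sets - length(sets)
  if (n_decoy_sets > 0L) {
    if (length(decoys) < n_decoy_sets)
      stop("annotation layout infeasible: not enough decoy genes for ",
           n_decoy_sets, " decoy sets", call. = FALSE)
    grp <- rep(seq_len(n_decoy_sets), length.out = length(decoys))
    grp <- sort(grp)
    for (s in seq_len(n_decoy_sets))
      sets[[sprintf("S%d", length(sets) + 1L)]] <- decoys[grp == s]
  }
  attr(sets, "description") <- stats::setNames(
    ifelse(names(sets) == truth_set %||% "", "planted_pathway", "decoy_pathway"),
    names(sets))
  list(genes = genes, sets = sets, truth_set = truth_set)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate paired detection/replication cohorts with shared annotation
#'
#' Both cohorts come from the same generating model: identical SNP panel,
#' MAFs, planted penetrance models and annotation, but independent genotype
#' and phenotype draws. The replication cohort is scaled by
#' `config$replication_fraction` (default half), mirroring the common design
#' where the replication GWAS is the smaller of the two.
#'
#' @param config A [sim_config()].
#' @return List with `detection` and `replication` ([cohort_data] objects),
#'   `genes`, `sets`, `truth_set` and `truth`.
#' @examples
#' sim <- simulate_paired_cohorts(sim_config(n_cases = 50, n_controls = 50,
#'                                           n_snps = 20, n_genes = 4,
#'                                           n_sets = 2, seed = 7))
#' sim$detection
#' @export
simulate_paired_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed, kind = "Mersenne-Twister")
  layout <- panel_layout(config)
  mafs <- draw_mafs(config)
  det <- draw_cohort(config, mafs, layout, config$n_cases, config$n_controls,
                     "detection")
  rep_cases <- max(1L, as.integer(round(config$n_cases * config$replication_fraction)))
  rep_ctrls <- max(1L, as.integer(round(config$n_controls * config$replication_fraction)))
  repl <- draw_cohort(config, mafs, layout, rep_cases, rep_ctrls, "replication")
  ann <- simulate_annotation(config, layout)
  list(detection = det, replication = repl,
       genes = ann$genes, sets = ann$sets, truth_set = ann$truth_set,
       truth = sim_truth(config, layout, mafs))
}
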