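#' Pipeline configuration
#'
#' Collects every input path and tuning parameter of the three-phase analysis
#' into one list, so a run is fully described (and reproducible) by its
#' configuration. All defaults are echoed into the run report.
#'
#' @param genotypes Path to the detection-cohort genotype file.
#' @param genotypes_replication Optional path to the replication cohort.
#' @param dialect Genotype dialect, `"tsv"` or `"plink_raw"`.
#' @param snp_map Path to the SNP map (required for Phase II coordinates).
#' @param map_dialect `"bim"`, `"map"` or `"tsv"`.
#' @param genes_bed Path to the gene annotation (BED, name in column 4).
#' @param sets_gmt Path to the gene sets (GMT).
#' @param n_permutations Permutation rounds for the null (default 1000).
#' @param mode Null mode, `"max"` (default) or `"pooled"`; see [mdr_scan()].
#' @param window SNP-to-gene window in bp (default 500000).
#' @param alpha Significance dichotomy used at every level (default 0.05).
#' @param maf_min Optional MAF filter for the scan (default 0 = off).
#' @param seed Integer seed.
#' @param out_dir Output directory for result TSVs and the JSON run report.
#' @return A list of class `pipeline_config`.
#' @seealso [validate_config()], [run_pipeline()], [read_pipeline_config()]
#' @export
pipeline_config <- function(genotypes, snp_map, genes_bed, sets_gmt,
                            out_dir, genotypes_replication = NULL,
                            dialect = "tsv", map_dialect = "map",
                            n_permutations = 1000L, mode = "max",
                            window = 500000L, alpha = 0.05, maf_min = 0,
                            seed = 1L) {
  structure(list(genotypes = genotypes,
                 genotypes_replication = genotypes_replication,
                 dialect = dialect, snp_map = snp_map,
                 map_dialect = map_dialect, genes_bed = genes_bed,
                 sets_gmt = sets_gmt,
                 n_permutations = as.integer(n_permutations), mode = mode,
                 window = as.numeric(window), alpha = as.numeric(alpha),
                 maf_min = as.numeric(maf_min), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML (or JSON) file
#'
#' Field names follow the arguments of [pipeline_config()]. Relative paths are
#' interpreted relative to the configuration file's directory.
#'
#' @param path Configuration file.
#' @param overrides Named list of field overrides (e.g. from CLI flags).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  cfg[names(overrides)] <- overrides
  base <- dirname(normalizePath(path))
  for (f in c("genotypes", "genotypes_replication", "snp_map", "genes_bed",
              "sets_gmt", "out_dir")) {
    if (!is.null(cfg[[f]]) && !grepl("^(/|[A-Za-z]:)", cfg[[f]]))
      cfg[[f]] <- file.path(base, cfg[[f]])
  }
  do.call(pipeline_config, cfg)
}

#' Validate a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @return Character vector of problems, each naming the offending field;
#'   empty when the configuration satisfies [run_pipeline()]'s preconditions.
#' @export
validate_config <- function(config) {
  problems <- character()
  p <- function(msg) problems <<- c(problems, msg)
  for (f in c("genotypes", "snp_map", "genes_bed", "sets_gmt")) {
    v <- config[[f]]
    if (is.null(v) || !is.character(v) || !file.exists(v))
      p(sprintf("%s: path missing or unreadable (%s)", f,
                if (is.null(v)) "NULL" else v))
  }
  v <- config$genotypes_replication
  if (!is.null(v) && !file.exists(v))
    p(sprintf("genotypes_replication: path unreadable (%s)", v))
  if (!config$dialect %in% c("tsv", "plink_raw"))
    p("dialect: must be 'tsv' or 'plink_raw'")
  if (!config$map_dialect %in% c("bim", "map", "tsv"))
    p("map_dialect: must be 'bim', 'map' or 'tsv'")
  if (!is.finite(config$alpha) || config$alpha <= 0 || config$alpha >= 1)
    p("alpha: must lie in (0, 1)")
  if (!is.finite(config$window) || config$window < 0)
    p("window: must be >= 0")
  if (is.na(config$n_permutations) || config$n_permutations < 1L)
    p("n_permutations: must be >= 1")
  if (!config$mode %in% c("max", "pooled"))
    p("mode: must be 'max' or 'pooled'")
  if (is.null(config$out_dir) || !nzchar(config$out_dir))
    p("out_dir: must be set")
  problems
}

#' Run the full three-phase pipeline
#'
#' Phase I: exhaustive pairwise MDR scan, permutation null, per-pair and
#' per-SNP empirical p-values. Phase II: window-based SNP-to-gene mapping and
#' gene-level Fisher overabundance test. Phase III: gene-set Fisher test and,
#' when a replication cohort is given, two-cohort replication of genes and
#' sets at `alpha`. All intermediate tables are written as TSV under
#' `out_dir` (suffixed by cohort), plus a JSON run report (`report.json`)
#' echoing the full configuration, stage counts and wall time. A rerun with
#' the same configuration and inputs is bit-identical apart from the report's
#' timestamp fields.
#'
#' @param config A [pipeline_config()].
#' @return The run report, invisibly (a list, also written as JSON).
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid pipeline configuration:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  t0 <- proc.time()[["elapsed"]]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- file.path(config$out_dir, "MANIFEST")
  writeLines("status: running", manifest)

  report <- list(package = "epienrich",
                 version = as.character(utils::packageVersion("epienrich")),
                 r_version = paste(R.version$major, R.version$minor, sep = "."),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 config = unclass(config))

  stage <- "read inputs"
  result <- tryCatch({
    snp_map <- read_snp_map(config$snp_map, config$map_dialect)
    genes <- read_bed_genes(config$genes_bed)
    sets <- read_gmt(config$sets_gmt)
    cohorts <- list(detection = read_genotypes(config$genotypes,
                                               config$dialect, snps = snp_map,
                                               cohort_id = "detection"))
    if (!is.null(config$genotypes_replication))
      cohorts$replication <- read_genotypes(config$genotypes_replication,
                                            config$dialect, snps = snp_map,
                                            cohort_id = "replication")

    per_cohort <- list()
    gene_results <- list()
    set_results <- list()
    for (nm in names(cohorts)) {
      co <- cohorts[[nm]]
      stage <- paste0("phase I (", nm, ")")
      message(sprintf("[%s] phase I: scanning %d SNP pairs, %d permutations (%s null)",
                      nm, choose(ncol(co$genotypes), 2), config$n_permutations,
                      config$mode))
      fit <- mdr_scan(co, n_permutations = config$n_permutations,
                      mode = config$mode,
                      seed = config$seed + match(nm, names(cohorts)) - 1L,
                      maf_min = config$maf_min)
      write_results_table(fit$pairs,
                          file.path(config$out_dir, paste0("pairs_", nm, ".tsv")))
      write_results_table(fit$snps,
                          file.path(config$out_dir, paste0("snp_pvalues_", nm, ".tsv")))

      stage <- paste0("phase II (", nm, ")")
      map <- map_snps_to_genes(co$snps, genes, window = config$window)
      genes_res <- gene_enrichment(map, fit$snps, alpha = config$alpha)
      write_results_table(genes_res,
                          file.path(config$out_dir, paste0("gene_enrichment_", nm, ".tsv")))
      message(sprintf("[%s] phase II: %d/%d genes with p <= %.3g", nm,
                      sum(genes_res$p_value <= config$alpha), nrow(genes_res),
                      config$alpha))

      stage <- paste0("phase III (", nm, ")")
      sets_res <- set_enrichment(sets, genes_res, alpha = config$alpha)
      write_results_table(sets_res,
                          file.path(config$out_dir, paste0("set_enrichment_", nm, ".tsv")))
      message(sprintf("[%s] phase III: %d/%d sets with p <= %.3g", nm,
                      sum(sets_res$p_value <= config$alpha), nrow(sets_res),
                      config$alpha))

      gene_results[[nm]] <- genes_res
      set_results[[nm]] <- sets_res
      per_cohort[[nm]] <- list(
        n_samples = nrow(co$genotypes), n_snps = ncol(co$genotypes),
        n_pairs = nrow(fit$pairs),
        n_snps_significant = sum(fit$snps$p_value <= config$alpha),
        n_genes_significant = sum(genes_res$p_value <= config$alpha),
        n_sets_significant = sum(sets_res$p_value <= config$alpha),
        top_set = sets_res$entity_id[1L], top_set_p = sets_res$p_value[1L])
    }

    out <- list(per_cohort = per_cohort)
    if (length(cohorts) == 2L) {
      stage <- "replication"
      rep_genes <- replicate_enrichment(gene_results$detection,
                                        gene_results$replication,
                                        alpha = config$alpha)
      rep_sets <- replicate_enrichment(set_results$detection,
                                       set_results$replication,
                                       alpha = config$alpha)
      utils::write.table(rep_genes,
                         file.path(config$out_dir, "replicated_genes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(rep_sets,
                         file.path(config$out_dir, "replicated_sets.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      message(sprintf("replication: %d gene(s), %d set(s) significant in both cohorts",
                      nrow(rep_genes), nrow(rep_sets)))
      out$replicated_genes <- rep_genes$entity_id
      out$replicated_sets <- rep_sets$entity_id
    }
    out
  }, error = function(e) {
    writeLines(c("status: incomplete", paste0("failed_stage: ", stage),
                 paste0("error: ", conditionMessage(e))), manifest)
    stop("pipeline aborted at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  report$results <- result
  report$wall_time_s <- proc.time()[["elapsed"]] - t0
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  writeLines(c("status: complete",
               paste0("files: ", paste(sort(list.files(config$out_dir)),
                                       collapse = " "))), manifest)
  invisible(report)
}
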