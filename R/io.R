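#' Read a case-control genotype matrix
#'
#' Supports two dialects. `"tsv"`: tab-separated with a header row; the first
#' two columns are `sample_id` and `phenotype` (coded 0/1 with 1 = case, or
#' 1/2 with 2 = case), remaining columns are SNPs coded 0/1/2 with `NA` for
#' missing. `"plink_raw"`: the whitespace-separated output of
#' `plink --recode A` with header `FID IID PAT MAT SEX PHENOTYPE` followed by
#' `snpid_allele` genotype columns; phenotype 1 = control, 2 = case, 0/-9 =
#' missing (such samples are dropped with a message).
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"plink_raw"`.
#' @param snps Optional SNP map (see [read_snp_map()]) giving coordinates for
#'   the SNPs in the file; matched by `snp_id`.
#' @param cohort_id Label for the returned cohort.
#' @return A [cohort_data] object; sample and SNP order follow the file.
#' @export
read_genotypes <- function(path, dialect = c("tsv", "plink_raw"),
                           snps = NULL, cohort_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(cohort_id))
    cohort_id <- sub("\\.[^.]*$", "", basename(path))

  if (dialect == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
    if (ncol(df) < 3L)
      stop("TSV genotype file needs sample_id, phenotype and >= 1 SNP column",
           call. = FALSE)
    sample_id <- as.character(df[[1L]])
    ph_raw <- df[[2L]]
    gcols <- df[-(1:2)]
    snp_ids <- names(gcols)
    geno <- as.matrix(gcols)
    phenotype <- decode_phenotype_tsv(ph_raw)
  } else {
    df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                            check.names = FALSE, na.strings = c("NA", ""))
    fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!identical(names(df)[1:6], fixed))
      stop("not a PLINK .raw header (expected FID IID PAT MAT SEX PHENOTYPE): ",
           path, call. = FALSE)
    sample_id <- as.character(df$IID)
    ph_raw <- suppressWarnings(as.numeric(df$PHENOTYPE))
    keep <- !is.na(ph_raw) & ph_raw %in% c(1, 2)
    if (any(!keep))
      message(sum(!keep), " sample(s) with missing phenotype dropped")
    phenotype <- ifelse(ph_raw[keep] == 2, "case", "control")
    gcols <- df[keep, -(1:6), drop = FALSE]
    sample_id <- sample_id[keep]
    # column names are snpid_countedallele; strip the allele suffix
    snp_ids <- sub("_[^_]*$", "", names(gcols))
    geno <- as.matrix(gcols)
  }

  check_genotype_codes(geno, path, header_lines = 1L)
  storage.mode(geno) <- "integer"
  if (anyDuplicated(snp_ids))
    stop("duplicate snp_id in ", path, ": ",
         snp_ids[duplicated(snp_ids)][1L], call. = FALSE)
  rownames(geno) <- sample_id
  colnames(geno) <- snp_ids

  if (!is.null(snps)) {
    snps <- validate_snp_map(snps)
    idx <- match(snp_ids, snps$snp_id)
    if (anyNA(idx))
      stop("SNP map lacks entries for: ",
           paste(utils::head(snp_ids[is.na(idx)], 3L), collapse = ", "),
           call. = FALSE)
    snps <- snps[idx, , drop = FALSE]
  }
  cohort_data(geno, phenotype, snps, cohort_id)
}

decode_phenotype_tsv <- function(ph_raw) {
  ph <- suppressWarnings(as.numeric(as.character(ph_raw)))
  if (anyNA(ph)) stop("non-numeric phenotype code in TSV", call. = FALSE)
  u <- sort(unique(ph))
  if (all(u %in% c(0, 1))) ifelse(ph == 1, "case", "control")
  else if (all(u %in% c(1, 2))) ifelse(ph == 2, "case", "control")
  else stop("phenotype must be coded {0,1} or {1,2}; saw: ",
            paste(u, collapse = ","), call. = FALSE)
}

check_genotype_codes <- function(geno, path, header_lines = 1L) {
  suppressWarnings(storage.mode(geno) <- "numeric")
  bad <- !is.na(geno) & !(geno %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    stop(sprintf("invalid genotype code '%s' in %s at line %d",
                 format(geno[idx[1L, 1L], idx[1L, 2L]]), path,
                 idx[1L, 1L] + header_lines), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a SNP map
#'
#' @param path File path.
#' @param dialect `"bim"` (chrom, snp_id, cM, pos, allele1, allele2),
#'   `"map"` (chrom, snp_id, cM, pos) or `"tsv"` (header with columns
#'   `snp_id`, `chrom`, `pos` and optional `allele_a`, `allele_b`).
#' @return Data frame of SNP records in file order with columns `snp_id`,
#'   `chrom`, `pos`, `allele_a`, `allele_b`.
#' @export
read_snp_map <- function(path, dialect = c("bim", "map", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  empty <- data.frame(snp_id = character(), chrom = character(),
                      pos = integer(), allele_a = character(),
                      allele_b = character(), stringsAsFactors = FALSE)
  if (dialect %in% c("bim", "map")) {
    if (file.size(path) == 0L) return(empty)
    df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
    ncols <- if (dialect == "bim") 6L else 4L
    if (ncol(df) != ncols)
      stop(sprintf("%s file must have %d columns, found %d: %s",
                   dialect, ncols, ncol(df), path), call. = FALSE)
    pos <- suppressWarnings(as.numeric(df[[4L]]))
    if (anyNA(pos))
      stop(sprintf("non-integer position at line %d of %s",
                   which(is.na(pos))[1L], path), call. = FALSE)
    out <- data.frame(snp_id = as.character(df[[2L]]),
                      chrom = as.character(df[[1L]]),
                      pos = as.integer(pos),
                      allele_a = if (dialect == "bim") as.character(df[[5L]]) else NA_character_,
                      allele_b = if (dialect == "bim") as.character(df[[6L]]) else NA_character_,
                      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (nrow(df) == 0L) return(empty)
    need <- c("snp_id", "chrom", "pos")
    if (!all(need %in% names(df)))
      stop("TSV SNP map needs columns snp_id, chrom, pos", call. = FALSE)
    pos <- suppressWarnings(as.numeric(df$pos))
    if (anyNA(pos))
      stop(sprintf("non-integer position at line %d of %s",
                   which(is.na(pos))[1L] + 1L, path), call. = FALSE)
    out <- data.frame(snp_id = as.character(df$snp_id),
                      chrom = as.character(df$chrom),
                      pos = as.integer(pos),
                      allele_a = if ("allele_a" %in% names(df)) as.character(df$allele_a) else NA_character_,
                      allele_b = if ("allele_b" %in% names(df)) as.character(df$allele_b) else NA_character_,
                      stringsAsFactors = FALSE)
  }
  validate_snp_map(out)
}

#' Read gene regions from a BED file
#'
#' BED uses half-open 0-based coordinates; they are converted to the 1-based
#' inclusive convention used throughout the package (`start_bed + 1`,
#' `end_bed`). The gene identifier is taken from column 4. Overlapping genes
#' are retained as-is (no merging).
#'
#' @param path BED3+ file with the gene name in column 4.
#' @return Data frame with columns `gene_id`, `chrom`, `start`, `stop`
#'   (1-based inclusive), one row per BED line, order preserved.
#' @export
read_bed_genes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), stop = integer(),
                      stringsAsFactors = FALSE))
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L)
    stop("BED gene annotation needs >= 4 columns (chrom start end name): ",
         path, call. = FALSE)
  start_bed <- as.numeric(df[[2L]]); end_bed <- as.numeric(df[[3L]])
  if (any(start_bed >= end_bed))
    stop(sprintf("BED start >= end at line %d of %s",
                 which(start_bed >= end_bed)[1L], path), call. = FALSE)
  out <- data.frame(gene_id = as.character(df[[4L]]),
                    chrom = as.character(df[[1L]]),
                    start = as.integer(start_bed + 1),
                    stop = as.integer(end_bed),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene_id))
    stop("duplicate gene_id in ", path, ": ",
         out$gene_id[duplicated(out$gene_id)][1L], call. = FALSE)
  out
}

#' Read gene sets from a GMT file
#'
#' GMT lines are `set_id <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#' Duplicate member genes within a line are deduplicated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of member gene ids; names are set
#'   ids, set descriptions are kept in the `"description"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- stats::setNames(list(), character())
    attr(out, "description") <- character()
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop(sprintf("GMT line %d has fewer than 3 fields", which(nf < 3L)[1L]),
         call. = FALSE)
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate set_id in ", path, ": ", ids[duplicated(ids)][1L],
         call. = FALSE)
  desc <- vapply(parts, `[[`, "", 2L)
  members <- lapply(parts, function(p) unique(p[-(1:2)]))
  out <- stats::setNames(members, ids)
  attr(out, "description") <- stats::setNames(desc, ids)
  out
}

#' Write a result table to TSV
#'
#' Rows are ordered by ascending p-value with ties broken by identifier, so
#' output is deterministic. P-values (and other non-integer numerics) are
#' written in full-precision scientific notation; a round-trip through
#' [read_results_table()] recovers them to better than 12 significant digits.
#'
#' @param results Data frame of homogeneous results (pair, SNP, gene or set
#'   level) containing a `p_value` and/or `statistic` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  results <- as.data.frame(results, stringsAsFactors = FALSE)
  id_cols <- intersect(c("entity_id", "snp_id", "snp_i", "snp_j", "set_id",
                         "gene_id"), names(results))
  keys <- list()
  if ("p_value" %in% names(results)) keys <- c(keys, list(results$p_value))
  for (ic in id_cols) keys <- c(keys, list(results[[ic]]))
  if (length(keys)) results <- results[do.call(order, keys), , drop = FALSE]

  fmt <- results
  for (nm in names(fmt)) {
    v <- fmt[[nm]]
    if (is.double(v) && !all(is.na(v) | v == round(v)))
      fmt[[nm]] <- sprintf("%.15e", v)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.table(fmt, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read back a table written by [write_results_table()]
#' @param path TSV path.
#' @return Data frame.
#' @export
read_results_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Writers for the standard input formats
#'
#' These let the synthetic-data generator serialize a cohort and its
#' annotation so the whole pipeline can be exercised through files.
#'
#' @param cohort A [cohort_data] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_data"))
  ids <- rownames(cohort$genotypes)
  if (is.null(ids)) ids <- sprintf("s%05d", seq_len(nrow(cohort$genotypes)))
  df <- data.frame(sample_id = ids,
                   phenotype = ifelse(cohort$phenotype == "case", 2L, 1L),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(cohort$genotypes))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @param snps SNP map data frame (`snp_id`, `chrom`, `pos`).
#' @export
write_snp_map <- function(snps, path) {
  snps <- validate_snp_map(snps)
  df <- data.frame(snps$chrom, snps$snp_id, 0, snps$pos)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @param genes Gene regions data frame (1-based inclusive `start`/`stop`);
#'   written as half-open 0-based BED.
#' @export
write_bed_genes <- function(genes, path) {
  df <- data.frame(genes$chrom, genes$start - 1L, genes$stop, genes$gene_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @param sets Named list of member-gene character vectors (see [read_gmt()]).
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, unname(desc[id]), sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
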