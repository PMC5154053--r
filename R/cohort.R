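#' Construct a case-control cohort
#'
#' Bundles a genotype matrix, phenotype labels and a SNP map into a validated
#' `cohort_data` object, the container every analysis function in this package
#' operates on.
#'
#' @param genotypes Integer matrix, samples in rows and SNPs in columns.
#'   Entries are minor-allele counts 0/1/2; `NA` marks a missing genotype.
#' @param phenotype Character vector of `"case"`/`"control"`, one per sample.
#' @param snps Data frame with one row per SNP and columns `snp_id`, `chrom`,
#'   `pos` (1-based base-pair position) and optionally `allele_a`, `allele_b`.
#'   May be `NULL` when no map is available (positions unknown); a placeholder
#'   map with `NA` coordinates is then built from the matrix column names.
#' @param cohort_id Character label for the cohort.
#'
#' @return An object of class `cohort_data`: a list with elements `genotypes`,
#'   `phenotype`, `snps` and `cohort_id`.
#'
#' @examples
#' g <- matrix(c(0L, 1L, 2L, 1L, 0L, 0L), nrow = 3,
#'             dimnames = list(NULL, c("rs1", "rs2")))
#' cohort_data(g, c("case", "control", "case"))
#' @export
cohort_data <- function(genotypes, phenotype, snps = NULL, cohort_id = "cohort") {
  if (!is.matrix(genotypes)) genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  bad <- !is.na(genotypes) & !(genotypes %in% 0:2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("genotype code outside {0,1,2,NA} at sample %d, SNP %d",
                 idx[1L], idx[2L]), call. = FALSE)
  }
  phenotype <- as.character(phenotype)
  if (length(phenotype) != nrow(genotypes))
    stop("phenotype length must equal the number of samples", call. = FALSE)
  if (!all(phenotype %in% c("case", "control")))
    stop("phenotype labels must be 'case' or 'control'", call. = FALSE)
  if (!any(phenotype == "case") || !any(phenotype == "control"))
    stop("cohort needs at least one case and one control", call. = FALSE)

  if (is.null(snps)) {
    ids <- colnames(genotypes)
    if (is.null(ids)) ids <- sprintf("snp%04d", seq_len(ncol(genotypes)))
    snps <- data.frame(snp_id = ids, chrom = NA_character_,
                       pos = NA_integer_, stringsAsFactors = FALSE)
  }
  snps <- validate_snp_map(snps)
  if (nrow(snps) != ncol(genotypes))
    stop("SNP map row count must equal the genotype column count", call. = FALSE)
  colnames(genotypes) <- snps$snp_id

  structure(list(genotypes = genotypes, phenotype = phenotype,
                 snps = snps, cohort_id = as.character(cohort_id)),
            class = "cohort_data")
}

validate_snp_map <- function(snps) {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos")
  miss <- setdiff(need, names(snps))
  if (length(miss))
    stop("SNP map lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  snps$snp_id <- as.character(snps$snp_id)
  snps$chrom <- as.character(snps$chrom)
  snps$pos <- as.integer(snps$pos)
  if (anyDuplicated(snps$snp_id))
    stop("duplicate snp_id in SNP map: ",
         snps$snp_id[duplicated(snps$snp_id)][1L], call. = FALSE)
  if (any(!is.na(snps$pos) & snps$pos < 1L))
    stop("SNP positions must be >= 1", call. = FALSE)
  if (any(!is.na(snps$chrom) & !nzchar(snps$chrom)))
    stop("chromosome labels must be non-empty", call. = FALSE)
  rownames(snps) <- NULL
  snps
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("<cohort_data '%s'>\n", x$cohort_id))
  cat(sprintf("  %d samples (%d cases, %d controls), %d SNPs\n",
              nrow(x$genotypes), sum(x$phenotype == "case"),
              sum(x$phenotype == "control"), ncol(x$genotypes)))
  nmiss <- sum(is.na(x$genotypes))
  if (nmiss > 0) cat(sprintf("  %d missing genotype calls\n", nmiss))
  invisible(x)
}

#' @export
dim.cohort_data <- function(x) dim(x$genotypes)

# strip an optional 'chr' prefix so mixed-dialect chromosome labels compare
norm_chrom <- function(x) sub("^[Cc][Hh][Rr]", "", as.character(x))
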