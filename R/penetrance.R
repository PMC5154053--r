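#' Two-locus penetrance model
#'
#' A penetrance model is a 3x3 table of disease probabilities indexed by the
#' genotypes (minor-allele counts 0/1/2) at two SNPs, together with the two
#' minor-allele frequencies. Under Hardy-Weinberg genotype weights the table
#' implies an overall prevalence and single-SNP marginal penetrances; a model
#' is "purely epistatic" when every marginal penetrance equals the prevalence,
#' so neither SNP carries a main effect.
#'
#' @param table 3x3 numeric matrix of disease probabilities in \[0, 1\];
#'   rows index the genotype at SNP A, columns at SNP B.
#' @param maf_a,maf_b Minor-allele frequencies in (0, 0.5\].
#' @return An object of class `penetrance_model` with elements `table`,
#'   `maf_a`, `maf_b`, `prevalence` (HWE-weighted mean penetrance) and
#'   `marginal_deviation` (max over the six single-SNP genotype margins of
#'   the absolute difference from the prevalence).
#' @seealso [xor_model()] for the checkerboard pure-epistasis construction.
#' @export
penetrance_model <- function(table, maf_a, maf_b) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(3L, 3L)))
    stop("penetrance table must be 3x3", call. = FALSE)
  if (any(table < 0 | table > 1))
    stop("penetrance entries must lie in [0, 1]", call. = FALSE)
  for (f in c(maf_a, maf_b))
    if (!is.finite(f) || f <= 0 || f > 0.5)
      stop("minor-allele frequencies must lie in (0, 0.5]", call. = FALSE)
  wa <- hwe_weights(maf_a); wb <- hwe_weights(maf_b)
  prevalence <- drop(wa %*% table %*% wb)
  margins_a <- drop(table %*% wb)   # penetrance given genotype at SNP A
  margins_b <- drop(wa %*% table)   # given genotype at SNP B
  dev <- max(abs(c(margins_a, margins_b) - prevalence))
  structure(list(table = table, maf_a = maf_a, maf_b = maf_b,
                 prevalence = prevalence, marginal_deviation = dev),
            class = "penetrance_model")
}

#' Hardy-Weinberg genotype weights
#' @param maf Minor-allele frequency.
#' @return Probabilities of genotypes 0, 1, 2 copies of the minor allele.
#' @export
hwe_weights <- function(maf) c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)

#' Checkerboard (XOR-style) pure-epistasis penetrance model
#'
#' Builds a two-locus penetrance table with no single-SNP main effect:
#' genotype combinations with odd `g_a + g_b` get penetrance
#' `prevalence + effect`; even combinations are lowered by an amount chosen so
#' that both single-SNP HWE-weighted marginal penetrances equal the prevalence
#' exactly. With `h = 2*maf*(1-maf)` the shared heterozygote frequency, the
#' four homozygote-homozygote cells get `prevalence - effect*h/(1-h)` and the
#' double-heterozygote cell `prevalence - effect*(1-h)/h`. Exact margin
#' cancellation requires the two SNPs to share the same heterozygote
#' frequency, which for MAFs in (0, 0.5] means `maf_a == maf_b`.
#'
#' @param prevalence Baseline disease probability in (0, 1).
#' @param effect Non-negative penetrance elevation of the odd-sum cells;
#'   `effect = 0` gives a uniform (null) table.
#' @param maf_a,maf_b Minor-allele frequencies in (0, 0.5]; must be equal.
#' @return A [penetrance_model] whose `marginal_deviation` is <= 1e-12.
#' @examples
#' m <- xor_model(prevalence = 0.5, effect = 0.25, maf_a = 0.5, maf_b = 0.5)
#' m$table
#' m$marginal_deviation
#' @export
xor_model <- function(prevalence, effect, maf_a, maf_b = maf_a) {
  if (!is.finite(prevalence) || prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie in (0, 1)", call. = FALSE)
  if (!is.finite(effect) || effect < 0)
    stop("effect must be non-negative", call. = FALSE)
  ha <- 2 * maf_a * (1 - maf_a); hb <- 2 * maf_b * (1 - maf_b)
  if (abs(ha - hb) > 1e-9)
    stop("pure checkerboard epistasis needs equal heterozygote frequency ",
         "at the two SNPs (use maf_a == maf_b)", call. = FALSE)
  h <- ha
  tab <- matrix(NA_real_, 3L, 3L)
  odd <- outer(0:2, 0:2, function(a, b) (a + b) %% 2L == 1L)
  tab[odd] <- prevalence + effect
  tab[!odd] <- prevalence - effect * h / (1 - h)
  tab[2L, 2L] <- prevalence - effect * (1 - h) / h
  if (any(tab < 0 | tab > 1))
    stop(sprintf(paste0("infeasible penetrance model: entries outside [0, 1] ",
                        "(range %.4f..%.4f); reduce effect or move prevalence ",
                        "away from 0/1"), min(tab), max(tab)), call. = FALSE)
  penetrance_model(tab, maf_a, maf_b)
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat("<penetrance_model>\n")
  cat(sprintf("  maf_a = %.3f, maf_b = %.3f, prevalence = %.4f\n",
              x$maf_a, x$maf_b, x$prevalence))
  cat(sprintf("  marginal deviation = %.3g\n", x$marginal_deviation))
  print(round(x$table, 4))
  invisible(x)
}
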