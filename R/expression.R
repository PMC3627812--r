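#' Count reads overlapping each gene model
#'
#' A read increments every gene it overlaps by at least one base. Counting is
#' strand-blind by default, matching an unstranded mRNA-seq protocol; reads
#' spanning a gene boundary are counted for both genes, and reads overlapping
#' no gene are ignored.
#'
#' @param alignments A [GenomicRanges::GRanges] of aligned read intervals.
#' @param annotation A [GenomicRanges::GRanges] of genes with a `gene_id`
#'   metadata column.
#' @param stranded If `TRUE`, only same-strand overlaps are counted.
#' @return A named integer vector of per-gene read counts.
#' @export
count_reads <- function(alignments, annotation, stranded = FALSE) {
  if (length(annotation) && any(GenomicRanges::width(annotation) <= 0))
    abort("annotation contains a gene with non-positive length")
  n <- GenomicRanges::countOverlaps(annotation, alignments,
                                    minoverlap = 1L,
                                    ignore.strand = !stranded)
  stats::setNames(as.integer(n), S4Vectors::mcols(annotation)$gene_id)
}

#' Reads per kilobase of gene model per million mapped reads
#'
#' `rpkm = count * 1e9 / (gene_length * total_mapped)`, normalizing for gene
#' size and library depth.
#'
#' @param count Read count(s) for the feature.
#' @param gene_length Feature length(s) in bases; must be positive.
#' @param total_mapped Total mapped reads in the library; must be positive.
#' @return Numeric RPKM value(s).
#' @examples
#' rpkm(1000, 1000, 1e6)  # 1000
#' @export
rpkm <- function(count, gene_length, total_mapped) {
  if (any(gene_length <= 0)) abort("gene_length must be positive")
  if (any(total_mapped <= 0)) abort("total_mapped must be positive")
  as.numeric(count) * 1e9 / (as.numeric(gene_length) * as.numeric(total_mapped))
}

#' One-degree-of-freedom chi-square test for a two-condition expression pair
#'
#' Goodness-of-fit chi-square of the observed pair `(a, b)` against equal
#' expected values `((a+b)/2, (a+b)/2)`, i.e. `X2 = (a-b)^2 / (a+b)`, with the
#' p-value from the upper tail of the chi-square distribution with 1 df and
#' Bonferroni adjustment over `n_tests`. Applied to RPKM values, this is the
#' depth- and length-normalized differential test used throughout the
#' pipeline. `a = b = 0` returns `p_raw = 1`.
#'
#' @param rpkm_ap,rpkm_gp Non-negative expression values for the two
#'   conditions (vectorized).
#' @param n_tests Bonferroni family size (>= 1).
#' @return A data frame with columns `statistic`, `p_raw`, `p_adj`.
#' @export
chi2_differential <- function(rpkm_ap, rpkm_gp, n_tests = 1L) {
  if (any(rpkm_ap < 0) || any(rpkm_gp < 0)) abort("expression values must be >= 0")
  if (n_tests < 1L) abort("n_tests must be >= 1")
  tot <- rpkm_ap + rpkm_gp
  stat <- ifelse(tot > 0, (rpkm_ap - rpkm_gp)^2 / tot, 0)
  p_raw <- ifelse(tot > 0, stats::pchisq(stat, df = 1, lower.tail = FALSE), 1)
  data.frame(statistic = stat, p_raw = p_raw,
             p_adj = pmin(1, p_raw * n_tests))
}

#' Classify a gene into a phase-program category
#'
#' A gene is expressed in a condition when its RPKM exceeds
#' `expressed_threshold` (strictly). Silent genes are expressed in neither
#' condition; `AP_only`/`GP_only` genes are expressed in exactly one; among
#' genes expressed in both, at least `fold` (default 5) ratio makes the gene
#' `AP_dominant` or `GP_dominant`, otherwise `shared`.
#'
#' @param rpkm_ap,rpkm_gp RPKM values (vectorized).
#' @param expressed_threshold RPKM above which a gene counts as expressed.
#' @param fold Dominance fold threshold (`>=` comparison).
#' @return Character vector of categories.
#' @export
classify_phase <- function(rpkm_ap, rpkm_gp, expressed_threshold = 50,
                           fold = 5) {
  ap <- rpkm_ap > expressed_threshold
  gp <- rpkm_gp > expressed_threshold
  out <- rep("shared", length(rpkm_ap))
  out[!ap & !gp] <- "silent"
  out[ap & !gp] <- "AP_only"
  out[!ap & gp] <- "GP_only"
  both <- ap & gp
  out[both & rpkm_ap >= fold * rpkm_gp] <- "AP_dominant"
  out[both & rpkm_gp >= fold * rpkm_ap] <- "GP_dominant"
  out
}

#' Build the per-gene expression table
#'
#' Counts reads per ORF in both conditions, computes RPKM, applies the
#' chi-square/Bonferroni differential test and the phase-category rules.
#'
#' @param ap_alignments,gp_alignments Read [GenomicRanges::GRanges] for the
#'   two conditions.
#' @param annotation Gene [GenomicRanges::GRanges] with `gene_id`.
#' @param total_ap,total_gp Library totals used as the RPKM denominator;
#'   default all reads in each alignment set.
#' @param expressed_threshold,fold Passed to [classify_phase()].
#' @param stranded Passed to [count_reads()].
#' @return A data frame (one row per gene): `gene_id`, `length`, `count_ap`,
#'   `count_gp`, `rpkm_ap`, `rpkm_gp`, `expressed_ap`, `expressed_gp`,
#'   `p_raw`, `p_adj`, `category`. The Bonferroni family size (genes with any
#'   reads) is attached as attribute `n_tests`.
#' @export
expression_table <- function(ap_alignments, gp_alignments, annotation,
                             total_ap = length(ap_alignments),
                             total_gp = length(gp_alignments),
                             expressed_threshold = 50, fold = 5,
                             stranded = FALSE) {
  if (length(annotation) == 0L) abort("annotation contains no genes")
  len <- GenomicRanges::width(annotation)
  count_ap <- count_reads(ap_alignments, annotation, stranded)
  count_gp <- count_reads(gp_alignments, annotation, stranded)
  rpkm_ap <- rpkm(count_ap, len, total_ap)
  rpkm_gp <- rpkm(count_gp, len, total_gp)
  n_tests <- max(1L, sum(count_ap + count_gp > 0))
  test <- chi2_differential(rpkm_ap, rpkm_gp, n_tests)
  out <- data.frame(
    gene_id = S4Vectors::mcols(annotation)$gene_id,
    length = len,
    count_ap = unname(count_ap), count_gp = unname(count_gp),
    rpkm_ap = unname(rpkm_ap), rpkm_gp = unname(rpkm_gp),
    expressed_ap = unname(rpkm_ap > expressed_threshold),
    expressed_gp = unname(rpkm_gp > expressed_threshold),
    p_raw = test$p_raw, p_adj = test$p_adj,
    category = classify_phase(rpkm_ap, rpkm_gp, expressed_threshold, fold))
  attr(out, "n_tests") <- n_tests
  out
}

#' Summarize phase-program category counts
#'
#' Reports per-category gene counts and the nearest-integer percentage each
#' category represents of the expressed (non-silent) genes.
#'
#' @param x Either an [expression_table()] data frame (with a `category`
#'   column) or a named integer vector of category counts.
#' @return A list with `counts` (named, all six categories), `percent_of_expressed`
#'   (named integer percents; silent reported as `NA`), `total_genes` and
#'   `total_expressed`.
#' @examples
#' program_summary(c(AP_only = 353, GP_only = 1557, AP_dominant = 114,
#'                   GP_dominant = 66, shared = 250, silent = 0))
#' @export
program_summary <- function(x) {
  counts <- if (is.data.frame(x)) {
    tab <- table(factor(x$category, levels = PROGRAMS))
    stats::setNames(as.integer(tab), PROGRAMS)
  } else {
    full <- stats::setNames(integer(length(PROGRAMS)), PROGRAMS)
    full[names(x)] <- as.integer(x)
    full
  }
  expressed <- sum(counts) - counts[["silent"]]
  pct <- percent_of(counts, expressed)
  pct <- stats::setNames(as.integer(pct), names(counts))
  pct[["silent"]] <- NA_integer_
  list(counts = counts, percent_of_expressed = pct,
       total_genes = sum(counts), total_expressed = expressed)
}

#' GC content of a sequence
#'
#' Fraction of G/C bases, case-insensitive; ambiguous (non-ACGT) characters
#' are excluded from both numerator and denominator.
#'
#' @param sequence A character string or [Biostrings::DNAString].
#' @return GC fraction in `[0, 1]`.
#' @export
gc_content <- function(sequence) {
  s <- toupper(as.character(sequence))
  if (nchar(s) == 0L) abort("sequence is empty")
  chars <- strsplit(s, "")[[1]]
  keep <- chars %in% c("A", "C", "G", "T")
  if (!any(keep)) abort("sequence contains no unambiguous bases")
  mean(chars[keep] %in% c("G", "C"))
}

#' GC content at third codon positions
#'
#' @param sequence Coding sequence with length divisible by 3.
#' @return GC fraction at every third base.
#' @export
gc3_content <- function(sequence) {
  s <- toupper(as.character(sequence))
  if (nchar(s) == 0L) abort("sequence is empty")
  if (nchar(s) %% 3L != 0L) abort("coding sequence length must be divisible by 3")
  chars <- strsplit(s, "")[[1]]
  third <- chars[seq(3L, length(chars), by = 3L)]
  keep <- third %in% c("A", "C", "G", "T")
  if (!any(keep)) abort("no unambiguous third-position bases")
  mean(third[keep] %in% c("G", "C"))
}

#' Compare GC content between two gene groups
#'
#' Two-sided Welch two-sample t-test on per-gene GC fractions, as used to
#' contrast attack-phase versus growth-phase gene sets.
#'
#' @param ap_values,gp_values Numeric vectors of per-gene GC fractions
#'   (each of length >= 2).
#' @return A list with `t` (statistic) and `p` (two-sided p-value).
#' @export
compare_gc <- function(ap_values, gp_values) {
  if (length(ap_values) < 2L || length(gp_values) < 2L)
    abort("each group needs at least 2 values")
  if (stats::sd(ap_values) == 0 && stats::sd(gp_values) == 0 &&
      isTRUE(all.equal(mean(ap_values), mean(gp_values))))
    return(list(t = 0, p = 1))
  tt <- stats::t.test(ap_values, gp_values, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value)
}
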