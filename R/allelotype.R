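# Gene-level allelotyping of padlock-captured SNP counts from a hybrid
# (129 x castaneus) cell line.  The long-format SNP count matrix has one
# row per SNP per sample: snp_id, gene, sample, count_129, count_cast.

check_snp_matrix <- function(x) {
  req <- c("snp_id", "gene", "sample", "count_129", "count_cast")
  if (!is.data.frame(x) || !all(req %in% names(x))) {
    stop("SNP count matrix must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(x$count_129 < 0) || any(x$count_cast < 0)) {
    stop("allele counts must be non-negative", call. = FALSE)
  }
  g <- unique(x[c("snp_id", "gene")])
  if (anyDuplicated(g$snp_id)) {
    stop("each SNP must map to exactly one gene", call. = FALSE)
  }
  invisible(x)
}

#' Zero out allele counts below the detection floor
#'
#' A per-allele read count below `min_reads` is considered undetected and
#' set to 0 ("less than" is strict: a count equal to `min_reads` is kept).
#' With `per_allele = FALSE` the rule is instead applied to the SNP's total
#' count (129 + cast), zeroing both alleles together.
#'
#' @param matrix Long-format SNP count matrix (see module description).
#' @param min_reads Detection floor (default 10).
#' @param per_allele Apply the rule per allele count (default) or per SNP
#'   total.
#' @return The matrix with sub-floor counts set to 0.
#' @export
#' @examples
#' m <- data.frame(snp_id = "s1", gene = "g1", sample = "a",
#'                 count_129 = 9L, count_cast = 20L)
#' filter_undetected(m)
filter_undetected <- function(matrix, min_reads = 10L, per_allele = TRUE) {
  check_snp_matrix(matrix)
  stopifnot(min_reads >= 0)
  if (per_allele) {
    matrix$count_129[matrix$count_129 < min_reads] <- 0L
    matrix$count_cast[matrix$count_cast < min_reads] <- 0L
  } else {
    zero <- (matrix$count_129 + matrix$count_cast) < min_reads
    matrix$count_129[zero] <- 0L
    matrix$count_cast[zero] <- 0L
  }
  matrix
}

#' Keep only SNPs detected in every required sample
#'
#' A SNP counts as detected in a sample when its post-filter total
#' (129 + cast) is non-zero there.  Only SNPs detected in *all*
#' `required_samples` are retained (the source study required all six
#' samples).
#'
#' @param matrix Long-format SNP count matrix, normally already passed
#'   through [filter_undetected()].
#' @param required_samples Character vector of sample labels; defaults to
#'   every sample present.
#' @return The matrix restricted to complete SNPs.
#' @export
require_complete <- function(matrix, required_samples = NULL) {
  check_snp_matrix(matrix)
  present <- unique(matrix$sample)
  if (is.null(required_samples)) required_samples <- present
  unknown <- setdiff(required_samples, present)
  if (length(unknown)) {
    stop("unknown sample label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sub <- matrix[matrix$sample %in% required_samples, , drop = FALSE]
  detected <- (sub$count_129 + sub$count_cast) > 0
  n_det <- tapply(detected, sub$snp_id, sum)
  n_smp <- tapply(sub$sample, sub$snp_id, function(s) length(unique(s)))
  ok <- names(n_det)[n_det == length(required_samples) &
                       n_smp == length(required_samples)]
  matrix[matrix$snp_id %in% ok, , drop = FALSE]
}

#' Pseudocounted log allelic-ratio score
#'
#' `score = log_b((count_129 + pc) / (count_cast + pc))`.  The pseudocount
#' (default 10) avoids division by zero; with it, a gene observed only from
#' the 129 allele at depth 990 scores exactly 2.0 in base 10, and equal
#' counts score 0.
#'
#' @param count_129,count_cast Aggregated allele counts (vectorised).
#' @param pseudocount Positive pseudocount added to both counts.
#' @param log_base Logarithm base (default 10; the source analysis wrote
#'   "Log" without a base).
#' @return Numeric score(s).
#' @export
#' @examples
#' allelotype_score(990, 0)   # 2
#' allelotype_score(40, 90)   # log10(50/100)
allelotype_score <- function(count_129, count_cast, pseudocount = 10,
                             log_base = 10) {
  stopifnot(pseudocount > 0, log_base > 0, log_base != 1)
  log((count_129 + pseudocount) / (count_cast + pseudocount), base = log_base)
}

#' Gene-level allelotype matrix
#'
#' Combines the read counts of all surviving SNPs of each gene, per sample,
#' removes genes on the escapee list, and scores each gene x sample cell
#' with [allelotype_score()].  Genes with no surviving SNP rows are simply
#' absent (a message is emitted when `escapees` removes genes).
#'
#' @param matrix Long-format SNP count matrix, normally after
#'   [filter_undetected()] and [require_complete()].
#' @param pseudocount,log_base Passed to [allelotype_score()].
#' @param escapees Character vector of genes known to escape XCI, removed
#'   before scoring.
#' @param gene_pos Optional `data.frame(gene, chrom, start)` used to order
#'   the rows by chromosomal position (1-based coordinates); otherwise
#'   genes are sorted by name.
#' @return A numeric matrix, genes x samples, of allelotype scores, with
#'   attributes `pseudocount`, `log_base`, and `totals` (a long data frame
#'   of the aggregated per-gene per-sample counts).
#' @export
gene_allelotype <- function(matrix, pseudocount = 10, log_base = 10,
                            escapees = character(), gene_pos = NULL) {
  check_snp_matrix(matrix)
  drop <- unique(matrix$gene[matrix$gene %in% escapees])
  if (length(drop)) {
    message("removing ", length(drop), " escapee gene(s): ",
            paste(sort(drop), collapse = ", "))
    matrix <- matrix[!matrix$gene %in% escapees, , drop = FALSE]
  }
  if (!nrow(matrix)) {
    return(structure(matrix(numeric(), 0, 0), pseudocount = pseudocount,
                     log_base = log_base,
                     totals = data.frame(gene = character(),
                                         sample = character(),
                                         total_129 = integer(),
                                         total_cast = integer())))
  }
  agg <- stats::aggregate(cbind(total_129 = count_129,
                                total_cast = count_cast) ~ gene + sample,
                          data = matrix, FUN = sum)
  agg$score <- allelotype_score(agg$total_129, agg$total_cast,
                                pseudocount, log_base)
  genes <- sort(unique(agg$gene), method = "radix")
  if (!is.null(gene_pos)) {
    stopifnot(all(c("gene", "chrom", "start") %in% names(gene_pos)))
    pos <- gene_pos[gene_pos$gene %in% genes, , drop = FALSE]
    missing_pos <- setdiff(genes, pos$gene)
    if (length(missing_pos)) {
      stop("no position for gene(s): ", paste(missing_pos, collapse = ", "),
           call. = FALSE)
    }
    pos <- pos[order(pos$chrom, pos$start, pos$gene, method = "radix"), ]
    genes <- pos$gene
  }
  samples <- sort(unique(agg$sample), method = "radix")
  out <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
  out[cbind(match(agg$gene, genes), match(agg$sample, samples))] <- agg$score
  structure(out, pseudocount = pseudocount, log_base = log_base,
            totals = agg[order(agg$gene, agg$sample, method = "radix"), ])
}
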