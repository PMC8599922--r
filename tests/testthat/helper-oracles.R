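# Independent brute-force oracles.  These deliberately avoid the package's
# own code paths (vectorised ranking, aggregate, prcomp) so that agreement
# is evidence, not tautology.

# Ordinal ranking by repeated max extraction, lexicographic tie-break.
brute_rank <- function(v) {
  ids <- names(v)
  r <- integer(length(v))
  names(r) <- ids
  remaining <- ids
  for (i in seq_along(v)) {
    mx <- max(v[remaining])
    best <- sort(remaining[v[remaining] == mx], method = "radix")[1]
    r[best] <- i
    remaining <- setdiff(remaining, best)
  }
  r
}

oracle_candidates <- function(flag, empty, threshold) {
  unique_to_flag <- sort(setdiff(names(flag), names(empty)),
                         method = "radix")
  shared <- intersect(names(flag), names(empty))
  if (length(shared)) {
    gains <- brute_rank(empty)[shared] - brute_rank(flag)[shared]
    gain_selected <- sort(shared[gains >= threshold], method = "radix")
  } else {
    gain_selected <- character()
  }
  list(unique_to_flag = unique_to_flag, gain_selected = gain_selected)
}

random_score_tables <- function(n_flag, n_empty, n_shared, tie_prob = 0.3) {
  pool <- sprintf("P%03d", seq_len(n_flag + n_empty))
  shared <- pool[seq_len(n_shared)]
  flag_ids <- c(shared, pool[n_shared + seq_len(n_flag - n_shared)])
  empty_ids <- c(shared,
                 pool[n_flag + seq_len(n_empty - n_shared)])
  # coarse integer scores so ties actually occur
  draw <- function(n) {
    s <- round(rlnorm(n, log(50), 1))
    ties <- runif(n) < tie_prob
    s[ties] <- sample(c(10, 50, 100), sum(ties), replace = TRUE)
    s
  }
  list(flag = setNames(draw(length(flag_ids)), flag_ids),
       empty = setNames(draw(length(empty_ids)), empty_ids))
}

# Recompute gene allelotype scores from raw SNP rows with explicit loops.
oracle_gene_scores <- function(counts, min_reads, required_samples,
                               pseudocount, log_base, escapees) {
  counts <- counts[!counts$gene %in% escapees, , drop = FALSE]
  for (i in seq_len(nrow(counts))) {
    if (counts$count_129[i] < min_reads) counts$count_129[i] <- 0L
    if (counts$count_cast[i] < min_reads) counts$count_cast[i] <- 0L
  }
  keep <- character()
  for (snp in unique(counts$snp_id)) {
    ok <- TRUE
    for (smp in required_samples) {
      row <- counts[counts$snp_id == snp & counts$sample == smp, ]
      if (nrow(row) == 0L || row$count_129 + row$count_cast == 0L) {
        ok <- FALSE
      }
    }
    if (ok) keep <- c(keep, snp)
  }
  counts <- counts[counts$snp_id %in% keep, , drop = FALSE]
  out <- list()
  for (g in sort(unique(counts$gene), method = "radix")) {
    for (smp in sort(unique(counts$sample), method = "radix")) {
      rows <- counts[counts$gene == g & counts$sample == smp, ]
      if (!nrow(rows)) next
      t129 <- sum(rows$count_129)
      tcast <- sum(rows$count_cast)
      out[[paste(g, smp, sep = "|")]] <-
        log((t129 + pseudocount) / (tcast + pseudocount)) / log(log_base)
    }
  }
  out
}

# Full eigen-decomposition PCA oracle on a small samples x positions matrix.
oracle_pca_scores <- function(x) {
  xc <- sweep(x, 2, colMeans(x))
  e <- eigen(crossprod(xc) / (nrow(x) - 1), symmetric = TRUE)
  scores <- xc %*% e$vectors
  list(scores = scores, values = e$values)
}
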