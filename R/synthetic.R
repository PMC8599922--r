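# Synthetic-data generators.  Each emits ground-truth-labelled inputs with
# the minimal standard statistical structure of the corresponding assay:
# heavy-tailed MS scores with a planted enriched subset, beta-binomial
# allelic counts with per-gene skew classes, Poisson insertion sites with a
# per-bin compaction factor, binomial mutation events over a true
# reactivity profile, and lognormal-noise first-order decay series.
# Identical seed + parameters give byte-identical output.

new_truth <- function(stage, parameters, truth, seed) {
  structure(list(stage = stage, parameters = parameters, truth = truth,
                 seed = seed),
            class = "xci_truth")
}

#' @export
print.xci_truth <- function(x, ...) {
  cat(sprintf("Synthetic truth for stage '%s' (seed %s)\n", x$stage,
              format(x$seed)))
  invisible(x)
}

#' Simulate two pulldown MS protein-score tables
#'
#' Background proteins draw scores independently in both samples from a
#' common heavy-tailed (lognormal) distribution.  True binders draw the
#' same background scores but are multiplied by `enrichment_factor` in the
#' tagged ("flag") sample only; `n_unique` additional binders appear only
#' in the flag table.
#'
#' @param n_background Number of background proteins (in both tables).
#' @param n_true_binders Number of enriched binders present in both tables.
#' @param n_unique Number of binders present only in the flag table.
#' @param score_shape Lognormal sdlog of the score distribution (default 1).
#' @param enrichment_factor Multiplier (>= 1) applied to binder scores in
#'   the flag sample (default 20).
#' @param seed Global seed; the interactome RNG stream is derived from it.
#' @return `list(flag, empty, truth)`: two `data.frame(protein_id, score)`
#'   tables and an `xci_truth` whose payload lists `binders` (all planted
#'   binders), `unique_to_flag`, and the enrichment factor.
#' @export
gen_ms_scores <- function(n_background, n_true_binders, n_unique = 0L,
                          score_shape = 1, enrichment_factor = 20,
                          seed = 1L) {
  if (n_background < 0 || n_true_binders < 0 || n_unique < 0) {
    stop("protein counts must be non-negative", call. = FALSE)
  }
  if (enrichment_factor < 1) {
    stop("enrichment_factor must be >= 1", call. = FALSE)
  }
  if (score_shape <= 0) stop("score_shape must be positive", call. = FALSE)
  params <- list(n_background = n_background, n_true_binders = n_true_binders,
                 n_unique = n_unique, score_shape = score_shape,
                 enrichment_factor = enrichment_factor)
  bg_ids <- sprintf("BG%04d", seq_len(n_background))
  bd_ids <- sprintf("XB%03d", seq_len(n_true_binders))
  uq_ids <- sprintf("UQ%03d", seq_len(n_unique))
  with_seed(stage_seed(seed, "interactome"), {
    draw <- function(n) stats::rlnorm(n, meanlog = log(100),
                                      sdlog = score_shape)
    flag <- data.frame(
      protein_id = c(bg_ids, bd_ids, uq_ids),
      score = c(draw(n_background),
                draw(n_true_binders) * enrichment_factor,
                draw(n_unique) * enrichment_factor))
    empty <- data.frame(
      protein_id = c(bg_ids, bd_ids),
      score = c(draw(n_background), draw(n_true_binders)))
  })
  truth <- new_truth("interactome", params,
                     list(binders = c(bd_ids, uq_ids),
                          unique_to_flag = uq_ids,
                          enrichment_factor = enrichment_factor),
                     seed)
  list(flag = flag, empty = empty, truth = truth)
}

rbetabinom <- function(n, size, prob, rho) {
  if (rho == 0) return(stats::rbinom(n, size, prob))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  stats::rbinom(n, size, stats::rbeta(n, a, b))
}

#' Simulate a padlock SNP-capture count matrix
#'
#' Genes are assigned to three allelic classes: `silenced` (129-allele
#' fraction drawn uniformly in 0.95-1, the inactivated castaneus X being
#' silent), `escapee` (fraction uniform in 0.3-0.7), and `biallelic`
#' (fraction 0.5).  Per SNP and sample, total depth is Poisson and the
#' 129-allele count is beta-binomial with intraclass correlation
#' `overdispersion`.
#'
#' @param n_genes Number of genes.
#' @param snps_per_gene SNPs per gene (default 4).
#' @param class_fractions Length-3 simplex `(silenced, escapee, biallelic)`
#'   (default `c(0.7, 0.15, 0.15)`); class counts are assigned by largest
#'   remainder so they are deterministic.
#' @param depth_mean Poisson mean per-SNP total depth (default 500).
#' @param overdispersion Beta-binomial intraclass correlation in `[0, 1)`
#'   (default 0.01).
#' @param n_samples Number of samples (default 6, as in the source assay).
#' @param seed Global seed.
#' @return `list(counts, gene_pos, truth)`: a long-format SNP count matrix
#'   (see [filter_undetected()]), a gene position table for row ordering,
#'   and an `xci_truth` recording each gene's class and true 129 fraction.
#' @export
gen_padlock_counts <- function(n_genes, snps_per_gene = 4L,
                               class_fractions = c(silenced = 0.7,
                                                   escapee = 0.15,
                                                   biallelic = 0.15),
                               depth_mean = 500, overdispersion = 0.01,
                               n_samples = 6L, seed = 1L) {
  if (length(class_fractions) != 3L || any(class_fractions < 0) ||
      abs(sum(class_fractions) - 1) > 1e-8) {
    stop("class_fractions must be a length-3 simplex summing to 1",
         call. = FALSE)
  }
  stopifnot(n_genes >= 1, snps_per_gene >= 1, depth_mean > 0,
            overdispersion >= 0, overdispersion < 1, n_samples >= 1)
  classes <- c("silenced", "escapee", "biallelic")
  # largest-remainder apportionment of genes to classes
  quota <- n_genes * class_fractions
  n_class <- floor(quota)
  rem <- n_genes - sum(n_class)
  if (rem > 0) {
    extra <- order(quota - n_class, decreasing = TRUE)[seq_len(rem)]
    n_class[extra] <- n_class[extra] + 1
  }
  gene_class <- rep(classes, times = n_class)
  genes <- sprintf("gene%03d", seq_len(n_genes))
  samples <- sprintf("s%d", seq_len(n_samples))
  with_seed(stage_seed(seed, "allelotype"), {
    p129 <- numeric(n_genes)
    p129[gene_class == "silenced"] <- stats::runif(n_class[1], 0.95, 1)
    p129[gene_class == "escapee"] <- stats::runif(n_class[2], 0.3, 0.7)
    p129[gene_class == "biallelic"] <- 0.5
    rows <- expand.grid(snp = seq_len(snps_per_gene),
                        gene_i = seq_len(n_genes),
                        sample = samples, stringsAsFactors = FALSE)
    n <- nrow(rows)
    depth <- stats::rpois(n, depth_mean)
    c129 <- rbetabinom(n, depth, p129[rows$gene_i], overdispersion)
  })
  counts <- data.frame(
    snp_id = sprintf("%s_snp%d", genes[rows$gene_i], rows$snp),
    gene = genes[rows$gene_i],
    sample = rows$sample,
    count_129 = as.integer(c129),
    count_cast = as.integer(depth - c129))
  gene_pos <- data.frame(gene = genes, chrom = "chrX",
                         start = seq_len(n_genes) * 1e6 + 1)
  truth <- new_truth(
    "allelotype",
    list(n_genes = n_genes, snps_per_gene = snps_per_gene,
         class_fractions = as.list(stats::setNames(class_fractions, classes)),
         depth_mean = depth_mean, overdispersion = overdispersion,
         n_samples = n_samples),
    list(gene = genes, class = gene_class, p129 = p129), seed)
  list(counts = counts, gene_pos = gene_pos, truth = truth)
}

resolve_factors <- function(chrom_sizes, bin_size, compaction_factors) {
  grid <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    data.frame(chrom = ch,
               bin_start = seq(0, chrom_sizes[[ch]] - 1, by = bin_size))
  }))
  grid$factor <- 1
  if (is.null(compaction_factors)) return(grid)
  if (is.data.frame(compaction_factors)) {
    key <- paste(grid$chrom, grid$bin_start)
    fk <- paste(compaction_factors$chrom, compaction_factors$bin_start)
    hit <- match(key, fk)
    grid$factor[!is.na(hit)] <- compaction_factors$factor[hit[!is.na(hit)]]
  } else if (!is.null(names(compaction_factors))) {
    for (ch in names(compaction_factors)) {
      grid$factor[grid$chrom == ch] <- compaction_factors[[ch]]
    }
  } else if (length(compaction_factors) == 1L) {
    grid$factor[] <- compaction_factors
  } else {
    stop("compaction_factors must be a scalar, a chromosome-named vector, ",
         "or a data.frame(chrom, bin_start, factor)", call. = FALSE)
  }
  if (any(grid$factor <= 0)) {
    stop("compaction factors must be positive", call. = FALSE)
  }
  grid
}

#' Simulate ATAC transposon insertion sites
#'
#' Per bin, the number of insertion events is Poisson with mean
#' `base_intensity * (bin width in Mb) * library_scale / factor`, so a
#' compaction factor of 2 halves the insertion intensity; positions are
#' uniform within the bin.  The autosomal (non-chrX) read total used for
#' depth normalisation is the realised number of autosomal insertions.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#'   Include at least one non-chrX chromosome to obtain a realised
#'   autosomal read total; otherwise a nominal `1e7 * library_scale` total
#'   is emitted.
#' @param base_intensity Insertion events per Mb at factor 1 (default
#'   2000).
#' @param compaction_factors Per-bin compaction factor: a scalar, a
#'   chromosome-named vector, or a `data.frame(chrom, bin_start, factor)`.
#'   `NULL` means 1 everywhere.
#' @param library_scale Global library-depth multiplier (default 1).
#' @param bin_size Bin width used to lay out intensities (default 1 Mb).
#' @param sample_label Sample name for the returned object.
#' @param seed Global seed.
#' @return `list(sites, truth)`: an [insertion_sites()] object and an
#'   `xci_truth` recording the per-bin factors.
#' @export
gen_atac_sites <- function(chrom_sizes, base_intensity = 2000,
                           compaction_factors = NULL, library_scale = 1,
                           bin_size = 1e6, sample_label = "sample",
                           seed = 1L) {
  stopifnot(is.numeric(chrom_sizes), !is.null(names(chrom_sizes)),
            base_intensity > 0, library_scale > 0, bin_size > 0)
  if (any(chrom_sizes <= 0)) {
    stop("zero-length chromosome in chrom_sizes", call. = FALSE)
  }
  grid <- resolve_factors(chrom_sizes, bin_size, compaction_factors)
  grid$width <- pmin(grid$bin_start + bin_size,
                     chrom_sizes[grid$chrom]) - grid$bin_start
  with_seed(stage_seed(seed, "atac"), {
    lambda <- base_intensity * (grid$width / 1e6) * library_scale /
      grid$factor
    n_bin <- stats::rpois(nrow(grid), lambda)
    pos <- unlist(lapply(seq_len(nrow(grid)), function(i) {
      if (n_bin[i] == 0L) return(integer())
      grid$bin_start[i] + sample.int(grid$width[i], n_bin[i],
                                     replace = TRUE) - 1L
    }))
  })
  sites_df <- data.frame(chrom = rep(grid$chrom, n_bin), pos = pos)
  autosomal <- sum(n_bin[grid$chrom != "chrX"])
  total <- if (autosomal > 0) autosomal else round(1e7 * library_scale)
  truth <- new_truth(
    "atac",
    list(base_intensity = base_intensity, library_scale = library_scale,
         bin_size = bin_size),
    list(factors = grid[c("chrom", "bin_start", "factor")],
         expected_per_bin = base_intensity * (grid$width / 1e6) *
           library_scale / grid$factor,
         total_autosomal_reads = total),
    seed)
  list(sites = insertion_sites(sites_df, total, sample_label), truth = truth)
}

md_from_mismatches <- function(read_len, mismatch_offsets) {
  # MD tag for an all-match read with mismatches at the given 1-based
  # offsets (reference base arbitrarily reported as A)
  if (!length(mismatch_offsets)) return(as.character(read_len))
  mismatch_offsets <- sort(mismatch_offsets)
  runs <- diff(c(0L, mismatch_offsets)) - 1L
  paste0(paste0(runs, "A", collapse = ""),
         read_len - mismatch_offsets[length(mismatch_offsets)])
}

#' Simulate SHAPE-MaP mutation-count profiles
#'
#' Control samples draw per-position mutation events
#' `Binomial(depth, background_rate)`; treated samples draw
#' `Binomial(depth, background_rate + true_reactivity)`.  With
#' `as_reads = TRUE` each sample is additionally emitted as minimal
#' full-length aligned-read records whose post-trim mutation counts equal
#' the drawn binomial counts exactly, exercising the counting path.
#'
#' @param seq_length Transcript length (nt).
#' @param true_reactivity Per-position true reactivity (scalar recycled or
#'   length `seq_length`); must satisfy
#'   `background_rate + max(true_reactivity) <= 1`.
#' @param background_rate Reverse-transcription/sequencing error rate
#'   (default 2e-4).
#' @param depth Reads per position: scalar, or length-`seq_length` vector
#'   (vector depth is incompatible with `as_reads`).
#' @param samples Character vector of conditions, each `"treated"` or
#'   `"control"`.
#' @param as_reads Also emit read records (and restrict event generation to
#'   the primer-trimmed interior, positions `primer_length + 1` to
#'   `seq_length - primer_length`).
#' @param primer_length Trim width used in reads mode (default 30).
#' @param min_depth Rate-reporting floor forwarded to the profiles.
#' @param seed Global seed.
#' @return `list(profiles, reads, truth)`: named list of [shape_profile()]s,
#'   a named list of read data frames (`NULL` unless `as_reads`), and an
#'   `xci_truth` recording the true reactivity and the drawn event counts.
#' @export
gen_shape_profiles <- function(seq_length, true_reactivity = 0,
                               background_rate = 2e-4, depth = 50000,
                               samples = c(treated = "treated",
                                           control = "control"),
                               as_reads = FALSE, primer_length = 30L,
                               min_depth = 5000L, seed = 1L) {
  stopifnot(seq_length >= 1, length(samples) >= 1)
  true_reactivity <- rep_len(true_reactivity, seq_length)
  if (background_rate < 0 || background_rate > 1 ||
      any(true_reactivity < 0) ||
      background_rate + max(true_reactivity) > 1) {
    stop("rates must lie in [0, 1] with background + max reactivity <= 1",
         call. = FALSE)
  }
  if (!all(samples %in% c("treated", "control"))) {
    stop("samples must be 'treated' or 'control'", call. = FALSE)
  }
  if (is.null(names(samples))) {
    names(samples) <- paste0(samples, seq_along(samples))
  }
  depth_vec <- rep_len(depth, seq_length)
  if (as_reads && length(unique(depth_vec)) != 1L) {
    stop("as_reads requires a scalar depth", call. = FALSE)
  }
  interior <- if (as_reads) {
    seq(primer_length + 1L, seq_length - primer_length)
  } else {
    seq_len(seq_length)
  }
  if (as_reads && primer_length * 2L >= seq_length) {
    stop("seq_length too short for the primer trim", call. = FALSE)
  }
  profiles <- list()
  reads <- if (as_reads) list() else NULL
  drawn <- list()
  with_seed(stage_seed(seed, "shape"), {
    for (nm in names(samples)) {
      rate <- rep(background_rate, seq_length)
      if (samples[[nm]] == "treated") rate <- rate + true_reactivity
      events <- integer(seq_length)
      events[interior] <- stats::rbinom(length(interior),
                                        depth_vec[interior],
                                        rate[interior])
      prof_depth <- depth_vec
      if (as_reads) {
        # depth outside the trimmed interior is zero on the counting path
        prof_depth <- integer(seq_length)
        prof_depth[interior] <- depth_vec[1L]
        n_reads <- depth_vec[1L]
        per_read <- vector("list", n_reads)
        for (j in interior[events[interior] > 0L]) {
          hit <- sample.int(n_reads, events[j])
          for (r in hit) per_read[[r]] <- c(per_read[[r]], j)
        }
        reads[[nm]] <- data.frame(
          pos = rep(1L, n_reads),
          cigar = rep(paste0(seq_length, "M"), n_reads),
          md = vapply(per_read, function(mm)
            md_from_mismatches(seq_length, mm), ""))
      }
      profiles[[nm]] <- shape_profile(
        prof_depth, events, sample_label = nm,
        condition = if (samples[[nm]] == "treated") "treated_1M7"
                    else "control_DMSO",
        min_depth = min_depth)
      drawn[[nm]] <- events
    }
  })
  truth <- new_truth(
    "shape",
    list(seq_length = seq_length, background_rate = background_rate,
         depth = depth, samples = as.list(samples), as_reads = as_reads,
         primer_length = primer_length),
    list(true_reactivity = true_reactivity, events = drawn,
         interior = range(interior)),
    seed)
  list(profiles = profiles, reads = reads, truth = truth)
}

#' Write simulated reads as a minimal SAM file
#'
#' @param reads A read data frame from [gen_shape_profiles()] (columns
#'   `pos`, `cigar`, `md`).
#' @param path Output path.
#' @param rname Reference name written in the records and `@SQ` header.
#' @param ref_length Reference length for the `@SQ` header.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, rname = "transcript",
                      ref_length = NULL) {
  if (is.null(ref_length)) {
    ref_length <- max(reads$pos + vapply(reads$cigar, function(cg) {
      p <- parse_cigar(cg)
      sum(p$len[p$op %in% c("M", "=", "X", "D", "N")])
    }, 0L)) - 1L
  }
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", rname, as.integer(ref_length)))
  body <- sprintf("r%06d\t0\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*\tMD:Z:%s",
                  seq_len(nrow(reads)), rname, reads$pos, reads$cigar,
                  reads$md)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Simulate a noisy first-order decay series
#'
#' `level(t) = n0 * exp(-k * max(0, t - lag_hours))` times lognormal noise
#' with coefficient of variation `noise_cv` (mean-one noise).
#'
#' @param n0 Initial level (default 1).
#' @param k Decay constant per hour (>= 0).
#' @param timepoints Hours (default `c(0, 1, 2, 3, 4, 6, 8)`, a typical
#'   transcription-blockade sampling grid).
#' @param noise_cv Lognormal noise CV (default 0.1).
#' @param lag_hours Initial lag before decay starts (default 0).
#' @param seed Global seed.
#' @return `list(series, truth)`: a [decay_series()] and an `xci_truth`
#'   recording `k`, the half-life `log(2)/k`, and the noiseless levels.
#' @export
gen_decay_series <- function(n0 = 1, k = 0.35,
                             timepoints = c(0, 1, 2, 3, 4, 6, 8),
                             noise_cv = 0.1, lag_hours = 0, seed = 1L) {
  if (k < 0) stop("decay constant k must be >= 0", call. = FALSE)
  stopifnot(n0 > 0, length(timepoints) >= 1, all(timepoints >= 0),
            noise_cv >= 0, lag_hours >= 0)
  timepoints <- sort(timepoints)
  clean <- n0 * exp(-k * pmax(0, timepoints - lag_hours))
  with_seed(stage_seed(seed, "decay"), {
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      noise <- stats::rlnorm(length(timepoints), -sdlog^2 / 2, sdlog)
    } else {
      noise <- rep(1, length(timepoints))
    }
  })
  series <- decay_series(timepoints, clean * noise)
  truth <- new_truth(
    "decay",
    list(n0 = n0, k = k, timepoints = timepoints, noise_cv = noise_cv,
         lag_hours = lag_hours),
    list(k = k, half_life = if (k > 0) log(2) / k else Inf,
         clean_levels = clean),
    seed)
  list(series = series, truth = truth)
}
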