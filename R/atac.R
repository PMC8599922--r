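# Chromatin-compaction scoring from ATAC-seq transposon insertion sites.
# The alignment position of each read marks one insertion event; the "Cut
# Count" of a 1-Mb bin is the number of distinct insertion sites inside it.
# Coordinates are BED-style 0-based half-open; strand is ignored.

#' Construct an insertion-site set
#'
#' @param sites `data.frame(chrom, pos)` of 0-based insertion positions.
#' @param total_autosomal_reads Number of reads with a single best alignment
#'   outside chromosome X; used for depth normalisation.
#' @param sample_label Free-text sample name.
#' @return An object of class `insertion_sites`.
#' @export
insertion_sites <- function(sites, total_autosomal_reads,
                            sample_label = "sample") {
  stopifnot(is.data.frame(sites), all(c("chrom", "pos") %in% names(sites)))
  if (length(total_autosomal_reads) != 1L || total_autosomal_reads <= 0) {
    stop("total_autosomal_reads must be a single positive count",
         call. = FALSE)
  }
  if (nrow(sites) && any(sites$pos < 0)) {
    stop("insertion positions must be >= 0", call. = FALSE)
  }
  structure(list(sites = sites[c("chrom", "pos")],
                 total_autosomal_reads = total_autosomal_reads,
                 sample_label = sample_label),
            class = "insertion_sites")
}

#' @export
print.insertion_sites <- function(x, ...) {
  cat(sprintf("Insertion sites '%s': %d sites on %d chromosome(s), %g autosomal reads\n",
              x$sample_label, nrow(x$sites), length(unique(x$sites$chrom)),
              x$total_autosomal_reads))
  invisible(x)
}

#' Depth-normalisation factor relative to a reference library
#'
#' @param sample An [insertion_sites()] object.
#' @param reference_total Autosomal read total of the reference sample.
#' @return `reference_total / total_autosomal_reads`.
#' @export
normalization_factor <- function(sample, reference_total) {
  stopifnot(inherits(sample, "insertion_sites"))
  if (length(reference_total) != 1L || reference_total <= 0) {
    stop("reference_total must be a single positive count", call. = FALSE)
  }
  reference_total / sample$total_autosomal_reads
}

#' Cut Counts per genomic bin
#'
#' Counts distinct insertion sites (default) or raw reads per half-open bin
#' `[bin_start, bin_start + bin_size)` over every chromosome in
#' `chrom_sizes`, including empty bins.  A position exactly at a bin
#' boundary belongs to the bin starting there.
#'
#' @param sites An [insertion_sites()] object.
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param bin_size Bin width in bp (default 1 Mb, as in the source assay).
#' @param reference_total Optional reference autosomal read total; when
#'   given, `normalized_cut_count = cut_count * reference_total /
#'   total_autosomal_reads`, otherwise the raw count is carried over.
#' @param distinct Count distinct `(chrom, pos)` sites (`TRUE`, the literal
#'   reading of "number of insertion sites") or every read (`FALSE`).
#' @return A `data.frame(chrom, bin_start, cut_count, normalized_cut_count)`
#'   with attribute `bin_size`, class `bin_profile`.
#' @export
bin_cut_counts <- function(sites, chrom_sizes, bin_size = 1e6,
                           reference_total = NULL, distinct = TRUE) {
  stopifnot(inherits(sites, "insertion_sites"), bin_size > 0,
            is.numeric(chrom_sizes), !is.null(names(chrom_sizes)))
  if (any(chrom_sizes <= 0)) {
    stop("zero-length chromosome in chrom_sizes", call. = FALSE)
  }
  s <- sites$sites
  unknown <- setdiff(unique(s$chrom), names(chrom_sizes))
  if (length(unknown)) {
    stop("site on chromosome absent from chrom_sizes: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  beyond <- s$pos >= chrom_sizes[s$chrom]
  if (any(beyond)) {
    i <- which(beyond)[1L]
    stop(sprintf("site beyond chromosome length: %s:%d (record %d)",
                 s$chrom[i], s$pos[i], i), call. = FALSE)
  }
  if (distinct) s <- unique(s)
  grid <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    data.frame(chrom = ch,
               bin_start = seq(0, chrom_sizes[[ch]] - 1, by = bin_size))
  }))
  key <- paste(grid$chrom, grid$bin_start)
  cnt <- table(paste(s$chrom, floor(s$pos / bin_size) * bin_size))
  grid$cut_count <- as.integer(cnt[key])
  grid$cut_count[is.na(grid$cut_count)] <- 0L
  factor <- if (is.null(reference_total)) 1 else
    reference_total / sites$total_autosomal_reads
  grid$normalized_cut_count <- grid$cut_count * factor
  structure(grid, bin_size = bin_size, sample_label = sites$sample_label,
            class = c("bin_profile", "data.frame"), row.names = seq_len(nrow(grid)))
}

#' Compaction score per bin
#'
#' The ratio of (pseudocounted, normalised) Cut Counts between the
#' uninduced sample and the induced sample.  Induction of silencing
#' compacts chromatin and depletes insertions, so scores above 1 indicate
#' compaction upon induction.
#'
#' @param uninduced,induced [bin_cut_counts()] profiles on the same bin
#'   grid.
#' @param pseudocount Added to both normalised counts (default 1); only
#'   matters for near-empty bins.
#' @return The bin grid with an added `compaction_score` column.
#' @export
compaction_score <- function(uninduced, induced, pseudocount = 1) {
  stopifnot(inherits(uninduced, "bin_profile"), inherits(induced, "bin_profile"),
            pseudocount >= 0)
  if (nrow(uninduced) != nrow(induced) ||
      !all(uninduced$chrom == induced$chrom) ||
      !all(uninduced$bin_start == induced$bin_start)) {
    stop("bin grids of the two profiles do not match", call. = FALSE)
  }
  out <- uninduced[c("chrom", "bin_start")]
  out$uninduced <- uninduced$normalized_cut_count
  out$induced <- induced$normalized_cut_count
  out$compaction_score <- (out$uninduced + pseudocount) /
    (out$induced + pseudocount)
  out
}

#' Categorise bins as transcribed, intergenic or mixed
#'
#' A bin is `transcribed` when the fraction of its width overlapped by
#' transcribed intervals is at least `cutoff` (inclusive), `intergenic`
#' when that fraction is at most `1 - cutoff`, and `mixed` otherwise.
#'
#' @param bins A [bin_cut_counts()] profile (or any data frame with
#'   `chrom`, `bin_start`, and attribute/argument `bin_size`).
#' @param transcribed_regions `data.frame(chrom, start, end)` of half-open
#'   0-based intervals (e.g. from [read_bed3()]).
#' @param cutoff Overlap-fraction cut-off in (0.5, 1] or exactly 0.5
#'   (default 0.5, at which every bin is transcribed or intergenic).
#' @param bin_size Bin width; taken from `bins`' attribute when absent.
#' @return Character vector of categories, one per bin row.
#' @export
categorize_bins <- function(bins, transcribed_regions, cutoff = 0.5,
                            bin_size = attr(bins, "bin_size")) {
  stopifnot(all(c("chrom", "bin_start") %in% names(bins)),
            all(c("chrom", "start", "end") %in% names(transcribed_regions)),
            cutoff >= 0.5, cutoff <= 1, !is.null(bin_size))
  frac <- numeric(nrow(bins))
  for (ch in unique(bins$chrom)) {
    tr <- transcribed_regions[transcribed_regions$chrom == ch, , drop = FALSE]
    idx <- which(bins$chrom == ch)
    if (!nrow(tr)) next
    # Half-open [start, end) -> closed 1-based IRanges
    ir <- IRanges::reduce(IRanges::IRanges(start = tr$start + 1, end = tr$end))
    bin_ir <- IRanges::IRanges(start = bins$bin_start[idx] + 1,
                               width = bin_size)
    ov <- IRanges::findOverlaps(bin_ir, ir)
    if (length(ov)) {
      w <- IRanges::width(IRanges::pintersect(
        bin_ir[S4Vectors::queryHits(ov)], ir[S4Vectors::subjectHits(ov)]))
      frac[idx] <- frac[idx] +
        as.numeric(tapply(w, factor(S4Vectors::queryHits(ov),
                                    levels = seq_along(bin_ir)), sum,
                          default = 0)) / bin_size
    }
  }
  ifelse(frac >= cutoff, "transcribed",
         ifelse(frac <= 1 - cutoff, "intergenic", "mixed"))
}
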