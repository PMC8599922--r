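# One-control SHAPE-MaP reactivity profiling.  Chemical adducts on the
# probed RNA are read out as reverse-transcription "mutation rates"; the
# reactivity of a position is the treated-sample rate minus the vehicle
# (DMSO) control rate, with no denatured-control denominator.
# Transcript positions are 1-based.

#' Construct a per-position mutation profile
#'
#' @param position 1-based positions (defaults to `seq_along(depth)`).
#' @param depth Read depth per position.
#' @param events Mutation-event count per position (`<= depth`).
#' @param sample_label Free-text sample name.
#' @param condition One of `"treated_1M7"`, `"treated_5NIA"`,
#'   `"control_DMSO"`, or `NA`.
#' @param min_depth Positions with `depth < min_depth` are flagged
#'   `low_depth` and get an `NA` mutation rate (software-level rate
#'   reporting floor, default 5000).
#' @return `data.frame(position, depth, events, rate, low_depth)` of class
#'   `shape_profile` with attributes `sample_label` and `condition`.
#' @export
shape_profile <- function(depth, events, position = seq_along(depth),
                          sample_label = "sample", condition = NA_character_,
                          min_depth = 5000L) {
  stopifnot(length(depth) == length(events), length(position) == length(depth))
  if (any(events > depth)) {
    stop("mutation events cannot exceed depth", call. = FALSE)
  }
  if (any(depth < 0) || any(events < 0)) {
    stop("depth and events must be non-negative", call. = FALSE)
  }
  low <- depth < min_depth
  rate <- ifelse(low | depth == 0, NA_real_, events / depth)
  structure(data.frame(position = as.integer(position),
                       depth = as.integer(depth),
                       events = as.integer(events),
                       rate = rate, low_depth = low),
            sample_label = sample_label, condition = condition,
            min_depth = min_depth,
            class = c("shape_profile", "data.frame"))
}

# ---- minimal SAM handling (only the fields needed for mutation counting) --

parse_cigar <- function(cigar) {
  m <- regmatches(cigar, gregexpr("([0-9]+)([MIDNSHP=X])", cigar))[[1]]
  if (!length(m) || paste(m, collapse = "") != cigar) {
    stop("malformed CIGAR: ", cigar, call. = FALSE)
  }
  list(len = as.integer(sub("[MIDNSHP=X]$", "", m)),
       op = sub("^[0-9]+", "", m))
}

# Mismatch reference positions from an MD tag, given the read's reference
# start and CIGAR.  MD runs over reference-consuming aligned bases (M/=/X)
# plus ^-prefixed deletions.
md_mismatch_positions <- function(md, ref_positions_m) {
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Za-z]+|[A-Za-z]", md))[[1]]
  i <- 0L  # index into ref_positions_m (aligned M/=/X reference positions)
  out <- integer()
  for (tok in toks) {
    if (grepl("^[0-9]+$", tok)) {
      i <- i + as.integer(tok)
    } else if (startsWith(tok, "^")) {
      # deletion: consumes reference but not M positions; already counted
      # as events via the CIGAR D op
    } else {
      i <- i + 1L
      out <- c(out, ref_positions_m[i])
    }
  }
  out
}

#' Read a minimal SAM file of transcript-aligned reads
#'
#' Only the fields needed for mutation counting are kept: the 1-based
#' alignment position, the CIGAR string, and the `MD:Z:` tag (mismatch
#' encoding).  Header lines are skipped; unmapped records (`*` CIGAR) are
#' skipped with a warning.
#'
#' @param path SAM path.
#' @return `data.frame(pos, cigar, md)`, one row per usable record.
#' @export
read_sam_min <- function(path) {
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(data.frame(pos = integer(), cigar = character(),
                      md = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, 0L) < 11L
  if (any(bad)) {
    warning(sum(bad), " malformed SAM record(s) skipped", call. = FALSE)
    fields <- fields[!bad]
    if (!length(fields)) stop("all SAM records malformed", call. = FALSE)
  }
  pos <- as.integer(vapply(fields, `[[`, "", 4L))
  cigar <- vapply(fields, `[[`, "", 6L)
  md <- vapply(fields, function(f) {
    tag <- grep("^MD:Z:", f[-(1:11)], value = TRUE)
    if (length(tag)) sub("^MD:Z:", "", tag[1L]) else NA_character_
  }, "")
  keep <- cigar != "*" & !is.na(pos)
  if (!all(keep)) {
    warning(sum(!keep), " unmapped SAM record(s) skipped", call. = FALSE)
  }
  data.frame(pos = pos[keep], cigar = cigar[keep], md = md[keep])
}

#' Count per-position depth and mutation events from aligned reads
#'
#' For each read the aligned reference footprint (positions consumed by
#' `M`/`=`/`X`/`D` CIGAR ops) is computed; the first and last
#' `primer_length` footprint positions are excluded (both ends when
#' `trim_both_ends`, only the 5' end otherwise), mirroring amplicon primer
#' trimming.  A mutation event is a mismatch (from the `MD` tag), a deleted
#' reference position, or an insertion (assigned to the aligned position
#' immediately 5' of it), collapsed to at most one event per reference
#' position per read.  Depth counts the post-trim footprint.
#'
#' @param reads Either a `data.frame(pos, cigar, md)` (1-based `pos`; `md`
#'   may be `NA` for no mismatches) or a path to a minimal SAM file.
#' @param transcript_length Transcript length in nt.
#' @param primer_length Number of aligned positions trimmed from each read
#'   end (default 30).
#' @param trim_both_ends Trim both ends (default) or only the 5' end.
#' @param min_depth Rate-reporting depth floor passed to [shape_profile()]
#'   (default 5000).
#' @param sample_label,condition Metadata forwarded to the profile.
#' @return A [shape_profile()] over positions `1..transcript_length`.
#' @export
count_mutations <- function(reads, transcript_length, primer_length = 30L,
                            trim_both_ends = TRUE, min_depth = 5000L,
                            sample_label = "sample",
                            condition = NA_character_) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_sam_min(reads)
  stopifnot(is.data.frame(reads), all(c("pos", "cigar") %in% names(reads)),
            transcript_length >= 1, primer_length >= 0)
  if (is.null(reads$md)) reads$md <- NA_character_
  depth <- integer(transcript_length)
  events <- integer(transcript_length)
  for (i in seq_len(nrow(reads))) {
    cg <- tryCatch(parse_cigar(reads$cigar[i]), error = function(e) NULL)
    if (is.null(cg)) {
      warning("skipping read ", i, ": malformed CIGAR", call. = FALSE)
      next
    }
    ref <- reads$pos[i]
    footprint <- integer()   # reference positions consumed by M/=/X/D
    m_positions <- integer() # reference positions of M/=/X only (MD frame)
    ev <- integer()
    for (k in seq_along(cg$op)) {
      op <- cg$op[k]; len <- cg$len[k]
      if (op %in% c("M", "=", "X")) {
        span <- ref:(ref + len - 1L)
        footprint <- c(footprint, span)
        m_positions <- c(m_positions, span)
        ref <- ref + len
      } else if (op == "D") {
        span <- ref:(ref + len - 1L)
        footprint <- c(footprint, span)
        ev <- c(ev, span)          # deleted reference bases are events
        ref <- ref + len
      } else if (op == "N") {
        ref <- ref + len
      } else if (op == "I") {
        if (length(footprint)) ev <- c(ev, footprint[length(footprint)])
        else ev <- c(ev, reads$pos[i]) # insertion before first aligned base
      }
      # S/H/P consume no reference
    }
    if (!is.na(reads$md[i]) && nzchar(reads$md[i])) {
      mm <- tryCatch(md_mismatch_positions(reads$md[i], m_positions),
                     error = function(e) NULL)
      if (is.null(mm) || anyNA(mm)) {
        warning("skipping read ", i, ": MD tag inconsistent with CIGAR",
                call. = FALSE)
        next
      }
      ev <- c(ev, mm)
    }
    # primer trimming on the aligned footprint
    n <- length(footprint)
    keep_from <- min(primer_length + 1L, n + 1L)
    keep_to <- if (trim_both_ends) n - primer_length else n
    if (keep_from > keep_to) next
    kept <- footprint[keep_from:keep_to]
    kept <- kept[kept >= 1L & kept <= transcript_length]
    if (!length(kept)) next
    depth[kept] <- depth[kept] + 1L
    ev <- unique(ev)
    ev <- ev[ev %in% kept]
    events[ev] <- events[ev] + 1L
  }
  shape_profile(depth, events, sample_label = sample_label,
                condition = condition, min_depth = min_depth)
}

#' One-control SHAPE reactivity
#'
#' `reactivity = rate(treated) - rate(control)`, positionwise, with no
#' denatured-control denominator.  Reactivity is defined (and `defined` is
#' `TRUE`) only where both samples have positive depth; rates flagged
#' low-depth propagate as `NA`.
#'
#' @param treated,control [shape_profile()] objects over the same
#'   transcript coordinates.
#' @return `data.frame(position, reactivity, defined)`.
#' @export
reactivity <- function(treated, control) {
  stopifnot(inherits(treated, "shape_profile"),
            inherits(control, "shape_profile"))
  if (nrow(treated) != nrow(control) ||
      !all(treated$position == control$position)) {
    stop("treated and control profiles are not on the same coordinate frame",
         call. = FALSE)
  }
  data.frame(position = treated$position,
             reactivity = treated$rate - control$rate,
             defined = treated$depth > 0 & control$depth > 0)
}

#' Profiled positions: cross-sample depth filter
#'
#' Positions covered by strictly more than `min_reads` reads in *every*
#' profile (the source analysis used >10 000 reads in each sample).
#'
#' @param profiles A list of [shape_profile()] objects.
#' @param min_reads Strict depth cut-off (default 10000).
#' @return Sorted integer vector of positions.
#' @export
profiled_positions <- function(profiles, min_reads = 10000L) {
  if (inherits(profiles, "shape_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1L)
  sets <- lapply(profiles, function(p) {
    stopifnot(inherits(p, "shape_profile"))
    p$position[p$depth > min_reads]
  })
  sort(Reduce(intersect, sets))
}

#' Positions with positive mutation rate
#'
#' A position is "positive" when its mutation rate strictly exceeds
#' `threshold` (default 0.1%, close to the Illumina sequencing error rate).
#' Positions with an `NA` rate (zero or low depth) are never positive.
#'
#' @param profile A [shape_profile()].
#' @param threshold Strict rate cut-off (default 0.001).
#' @return Sorted integer vector of positions.
#' @export
positive_calls <- function(profile, threshold = 0.001) {
  stopifnot(inherits(profile, "shape_profile"), threshold >= 0)
  sort(profile$position[!is.na(profile$rate) & profile$rate > threshold])
}

#' PCA of reactivity profiles across samples
#'
#' Mean-centred (unscaled) principal component analysis of the sample x
#' position reactivity matrix, restricted to `restrict_to` positions.
#' Component signs follow a deterministic convention: the largest-magnitude
#' loading of each component is positive.
#'
#' @param reactivities Named list of [reactivity()] data frames (or a
#'   numeric sample x position matrix).
#' @param restrict_to Positions to use (e.g. from [profiled_positions()]);
#'   defaults to positions defined in every profile.
#' @return A list of class `xci_pca` with `scores` (sample x component),
#'   `loadings`, and `explained_variance` (fractions, non-increasing).
#' @export
pca_profiles <- function(reactivities, restrict_to = NULL) {
  if (is.matrix(reactivities)) {
    x <- reactivities
    if (!is.null(restrict_to)) x <- x[, as.character(restrict_to), drop = FALSE]
  } else {
    stopifnot(is.list(reactivities))
    if (length(reactivities) < 2L) {
      stop("PCA needs at least 2 samples", call. = FALSE)
    }
    if (is.null(restrict_to)) {
      restrict_to <- Reduce(intersect, lapply(reactivities, function(r)
        r$position[r$defined & !is.na(r$reactivity)]))
    }
    restrict_to <- sort(restrict_to)
    if (!length(restrict_to)) stop("empty restriction set", call. = FALSE)
    x <- t(vapply(reactivities, function(r) {
      r$reactivity[match(restrict_to, r$position)]
    }, numeric(length(restrict_to))))
    colnames(x) <- restrict_to
    if (is.null(rownames(x))) {
      rownames(x) <- names(reactivities) %||%
        paste0("sample", seq_len(nrow(x)))
    }
  }
  if (nrow(x) < 2L) stop("PCA needs at least 2 samples", call. = FALSE)
  if (anyNA(x)) stop("NA reactivity inside the restriction set", call. = FALSE)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  # deterministic sign convention
  for (k in seq_len(ncol(p$rotation))) {
    j <- which.max(abs(p$rotation[, k]))
    if (p$rotation[j, k] < 0) {
      p$rotation[, k] <- -p$rotation[, k]
      p$x[, k] <- -p$x[, k]
    }
  }
  tot <- sum(p$sdev^2)
  ev <- if (tot > 0) p$sdev^2 / tot else rep(0, length(p$sdev))
  structure(list(scores = p$x, loadings = p$rotation,
                 explained_variance = ev),
            class = "xci_pca")
}

#' @export
print.xci_pca <- function(x, ...) {
  cat("PCA of", nrow(x$scores), "reactivity profiles\n")
  cat("explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
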