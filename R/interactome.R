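# Candidate selection from two affinity-pulldown MS score tables.
# A protein score is the sum of the ion scores of its identified peptides;
# ranks are within-sample, rank 1 = highest score.

as_score_vector <- function(table) {
  if (is.data.frame(table)) {
    stopifnot(all(c("protein_id", "score") %in% names(table)))
    v <- as.numeric(table$score)
    names(v) <- as.character(table$protein_id)
  } else if (is.numeric(table) && (!is.null(names(table)) ||
                                   length(table) == 0L)) {
    v <- table
  } else {
    stop("score table must be a data.frame(protein_id, score) or a named ",
         "numeric vector", call. = FALSE)
  }
  if (anyDuplicated(names(v))) {
    stop("duplicate protein IDs in score table", call. = FALSE)
  }
  if (any(v < 0)) stop("protein scores must be non-negative", call. = FALSE)
  v
}

#' Rank proteins by MS protein score within one sample
#'
#' Rank 1 is the highest score; ranks run 1..N with no gaps.  Ties are
#' broken lexicographically by protein ID (C locale) so results are
#' deterministic.
#'
#' @param table A `data.frame` with columns `protein_id`, `score`, or a
#'   named numeric vector of scores.
#' @return A named integer vector of ranks.
#' @export
#' @examples
#' rank_by_score(c(A = 100, B = 50, C = 10))
rank_by_score <- function(table) {
  v <- as_score_vector(table)
  if (!length(v)) stop("empty score table", call. = FALSE)
  ord <- order(-v, names(v), method = "radix")
  r <- integer(length(v))
  r[ord] <- seq_along(v)
  names(r) <- names(v)
  r
}

#' Ranking gains between a tagged and a control pulldown
#'
#' For every protein identified in *both* samples, the gain is its rank in
#' the control (`empty`) table minus its rank in the tagged (`flag`) table,
#' each rank computed over that sample's full table.  A large positive gain
#' means the protein moved up strongly in the tagged pulldown.
#'
#' @param flag,empty Score tables (see [rank_by_score()]).
#' @return A `data.frame` with columns `protein_id`, `rank_flag`,
#'   `rank_empty`, `gain`, sorted by decreasing gain (ties by protein ID).
#'   Disjoint tables yield zero rows.
#' @export
#' @examples
#' ranking_gains(c(A = 100, B = 10), c(A = 10, B = 100))
ranking_gains <- function(flag, empty) {
  fv <- as_score_vector(flag)
  ev <- as_score_vector(empty)
  shared <- intersect(names(fv), names(ev))
  if (!length(shared)) {
    return(data.frame(protein_id = character(), rank_flag = integer(),
                      rank_empty = integer(), gain = integer()))
  }
  rf <- rank_by_score(fv)[shared]
  re <- rank_by_score(ev)[shared]
  out <- data.frame(protein_id = shared,
                    rank_flag = unname(rf),
                    rank_empty = unname(re),
                    gain = unname(re - rf))
  out[order(-out$gain, out$protein_id, method = "radix"), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' Select candidate binding proteins
#'
#' Candidates are the union of (i) proteins identified only in the tagged
#' pulldown, and (ii) proteins identified in both samples whose ranking gain
#' is greater than or equal to `gain_threshold` (inclusive).
#'
#' @inheritParams ranking_gains
#' @param gain_threshold Integer gain cut-off (inclusive).  The study that
#'   motivated this package anchored it at 11, the gain of the known binder
#'   hnRNPM.
#' @return An object of class `candidate_set`: a list with elements
#'   `unique_to_flag`, `gain_selected` (disjoint character vectors),
#'   `candidates` (their union), `threshold`, and `gains` (the full
#'   [ranking_gains()] table).
#' @export
#' @examples
#' select_candidates(c(A = 100, B = 10, U = 5), c(A = 10, B = 100),
#'                   gain_threshold = 1)
select_candidates <- function(flag, empty, gain_threshold = 11L) {
  stopifnot(length(gain_threshold) == 1L,
            gain_threshold == round(gain_threshold))
  fv <- as_score_vector(flag)
  ev <- as_score_vector(empty)
  unique_to_flag <- sort(setdiff(names(fv), names(ev)), method = "radix")
  gains <- ranking_gains(fv, ev)
  gain_selected <- sort(gains$protein_id[gains$gain >= gain_threshold],
                        method = "radix")
  structure(
    list(unique_to_flag = unique_to_flag,
         gain_selected = gain_selected,
         candidates = c(unique_to_flag, gain_selected),
         threshold = as.integer(gain_threshold),
         gains = gains),
    class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf(
    "Candidate set: %d proteins (%d unique to tagged pulldown, %d with rank gain >= %d)\n",
    length(x$candidates), length(x$unique_to_flag),
    length(x$gain_selected), x$threshold))
  invisible(x)
}
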