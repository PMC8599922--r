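# RNG plumbing: one user-facing seed split into independent per-stage
# streams, so a single pipeline seed regenerates any stage on its own.

.stage_offsets <- c(
  interactome = 101L,
  allelotype  = 211L,
  atac        = 307L,
  shape       = 401L,
  decay       = 503L
)

#' Derive a per-stage RNG seed from a global seed
#'
#' Each synthetic-data generator draws from its own RNG stream so that
#' regenerating one stage does not perturb another.  The derived seed is a
#' deterministic function of the global seed and the stage name and always
#' fits in a 32-bit integer.
#'
#' @param seed Integer global seed.
#' @param stage One of `"interactome"`, `"allelotype"`, `"atac"`, `"shape"`,
#'   `"decay"`.
#' @return An integer seed.
#' @export
#' @examples
#' stage_seed(1, "atac")
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stage <- match.arg(stage, names(.stage_offsets))
  # 48271 is the classic Lehmer multiplier; products stay below 2^53.
  as.integer((abs(seed) * 48271 + .stage_offsets[[stage]]) %%
               (.Machine$integer.max - 1L) + 1L)
}

# Evaluate `code` under `set.seed(seed)` and restore the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}
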