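# Transcript decay kinetics after transcription blockade, plus the
# cell-survival ratio used to score induced-silencing toxicity.

#' Construct a decay series
#'
#' @param time_h Timepoints in hours, strictly increasing.
#' @param level Normalised expression levels, strictly positive.
#' @param replicate_id Optional replicate label.
#' @return `data.frame(time_h, level)` of class `decay_series`.
#' @export
decay_series <- function(time_h, level, replicate_id = NA_character_) {
  stopifnot(length(time_h) == length(level))
  if (is.unsorted(time_h, strictly = TRUE)) {
    stop("timepoints must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(level)) || any(level <= 0)) {
    stop("levels must be finite and positive", call. = FALSE)
  }
  structure(data.frame(time_h = time_h, level = level),
            replicate_id = replicate_id,
            class = c("decay_series", "data.frame"))
}

#' Normalise qPCR Cq values into a decay series
#'
#' Standard delta-Cq quantification: `level(t) =
#' efficiency^-(target_cq(t) - reference_cq(t))`, rescaled so the first
#' timepoint is 1.  The reference gene (Actb in the source study) controls
#' for input amount.
#'
#' @param time_h Timepoints in hours.
#' @param target_cq,reference_cq Matched Cq values.
#' @param efficiency Amplification efficiency (default 2, i.e. 100%).
#' @param replicate_id Optional replicate label.
#' @return A [decay_series()].
#' @export
normalize_series <- function(time_h, target_cq, reference_cq,
                             efficiency = 2, replicate_id = NA_character_) {
  stopifnot(length(time_h) == length(target_cq), efficiency > 1)
  if (length(reference_cq) != length(target_cq) || anyNA(reference_cq)) {
    stop("missing reference Cq value(s)", call. = FALSE)
  }
  if (anyNA(target_cq)) stop("missing target Cq value(s)", call. = FALSE)
  ord <- order(time_h)
  level <- efficiency^-(target_cq[ord] - reference_cq[ord])
  decay_series(time_h[ord], level / level[1L], replicate_id)
}

fit_loglinear <- function(time_h, level, min_points = 3L) {
  if (length(time_h) < min_points) return(NULL)
  fit <- stats::lm(log(level) ~ time_h)
  k <- -unname(stats::coef(fit)[2L])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(r2)) r2 <- NA_real_   # zero-variance response
  list(n0 = exp(unname(stats::coef(fit)[1L])), k = k, r2 = r2)
}

#' Fit a first-order exponential decay model
#'
#' Fits `level = n0 * exp(-k t)` by least squares on the log-transformed
#' levels (a nonlinear least-squares refinement is available with
#' `method = "nls"`; both agree on noiseless data).  R-squared is reported
#' on the fitted (log) scale.  A fitted `k <= 0` is flagged `no_decay` with
#' an infinite half-life.
#'
#' @param series A [decay_series()].
#' @param include_t0 Keep the earliest timepoint (default); `FALSE` drops
#'   it before fitting, as when an initial lag phase is suspected.
#' @param method `"loglinear"` (default) or `"nls"`.
#' @return A list of class `decay_fit`: `n0`, `k` (per hour), `half_life`
#'   (`log(2)/k`, hours), `r_squared`, `no_decay`, `points_used`.
#' @export
#' @examples
#' s <- decay_series(0:4, exp(-log(2) * (0:4)))
#' fit_decay(s)$half_life  # 1
fit_decay <- function(series, include_t0 = TRUE,
                      method = c("loglinear", "nls")) {
  stopifnot(inherits(series, "decay_series"))
  method <- match.arg(method)
  d <- series
  if (!include_t0) d <- d[-1L, , drop = FALSE]
  if (nrow(d) < 3L) {
    stop("need at least 3 points after optional t0 exclusion", call. = FALSE)
  }
  f <- fit_loglinear(d$time_h, d$level)
  if (method == "nls") {
    nl <- tryCatch(
      stats::nls(level ~ n0 * exp(-k * time_h), data = d,
                 start = list(n0 = f$n0, k = max(f$k, 1e-6))),
      error = function(e) NULL)
    if (!is.null(nl)) {
      cf <- stats::coef(nl)
      f$n0 <- unname(cf["n0"]); f$k <- unname(cf["k"])
    }
  }
  no_decay <- f$k <= 0
  structure(list(n0 = f$n0, k = f$k,
                 half_life = if (no_decay) Inf else log(2) / f$k,
                 r_squared = f$r2, no_decay = no_decay,
                 points_used = d$time_h, method = method),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$no_decay) {
    cat("Decay fit: no decay detected (k <= 0)\n")
  } else {
    cat(sprintf("Decay fit: k = %.4f /h, half-life = %.2f h, R^2 = %s (%d points)\n",
                x$k, x$half_life,
                ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared)),
                length(x$points_used)))
  }
  invisible(x)
}

#' Two-phase decay fit
#'
#' Splits the series at `breakpoint` (the source analysis treated the first
#' hour as a transient slow phase) and fits each phase independently.
#' Phase 1 uses points with `t <= breakpoint` (at least 2), phase 2 points
#' with `t > breakpoint` (at least 3); phase 2 re-anchors `n0` at its first
#' timepoint by shifting the time origin there.  A phase with too few
#' points is omitted with a warning.
#'
#' @param series A [decay_series()].
#' @param breakpoint Phase boundary in hours (default 1).
#' @return `list(phase1, phase2)` of `decay_fit` objects (either may be
#'   `NULL`).
#' @export
two_phase_fit <- function(series, breakpoint = 1) {
  stopifnot(inherits(series, "decay_series"))
  d1 <- series[series$time_h <= breakpoint, , drop = FALSE]
  d2 <- series[series$time_h > breakpoint, , drop = FALSE]
  phase1 <- phase2 <- NULL
  if (nrow(d1) >= 2L) {
    f <- fit_loglinear(d1$time_h, d1$level, min_points = 2L)
    phase1 <- structure(list(n0 = f$n0, k = f$k,
                             half_life = if (f$k <= 0) Inf else log(2) / f$k,
                             r_squared = f$r2, no_decay = f$k <= 0,
                             points_used = d1$time_h, method = "loglinear"),
                        class = "decay_fit")
  } else {
    warning("phase 1 omitted: fewer than 2 points at or before breakpoint",
            call. = FALSE)
  }
  if (nrow(d2) >= 3L) {
    t0 <- d2$time_h[1L]
    f <- fit_loglinear(d2$time_h - t0, d2$level)
    phase2 <- structure(list(n0 = f$n0, k = f$k,
                             half_life = if (f$k <= 0) Inf else log(2) / f$k,
                             r_squared = f$r2, no_decay = f$k <= 0,
                             points_used = d2$time_h, method = "loglinear",
                             anchor_time = t0),
                        class = "decay_fit")
  } else {
    warning("phase 2 omitted: fewer than 3 points after breakpoint",
            call. = FALSE)
  }
  list(phase1 = phase1, phase2 = phase2)
}

#' Cell survival rate under induction
#'
#' The ratio of cell numbers with and without induction (+Dox / -Dox), the
#' readout used to quantify the toxicity of induced silencing.
#'
#' @param n_plus_dox,n_minus_dox Cell counts.
#' @return `n_plus_dox / n_minus_dox`.
#' @export
#' @examples
#' survival_rate(40, 100)  # 0.4
survival_rate <- function(n_plus_dox, n_minus_dox) {
  stopifnot(n_plus_dox >= 0)
  if (length(n_minus_dox) != 1L || n_minus_dox <= 0) {
    stop("cell count without Dox must be positive", call. = FALSE)
  }
  n_plus_dox / n_minus_dox
}
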