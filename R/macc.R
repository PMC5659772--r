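# The accessibility statistic: per-bin regression slope across the
# MNase titration, GC correction and score-level validations.

#' Compute per-bin accessibility (MACC) scores
#'
#' For every bin, fits an ordinary least-squares line of normalized read
#' frequency against x = -log(concentration) and reports the slope. Open
#' chromatin is digested readily at low MNase and over-digested at high
#' MNase, so high frequency at low concentration gives a positive slope
#' (positive score); protected chromatin gives a negative score.
#'
#' The choice of logarithm base rescales all scores by a constant and does
#' not affect any downstream comparison; the natural log is the default.
#'
#' @param tc a normalized `titration_counts` (see [normalize_library()])
#'   with at least two distinct concentrations.
#' @param log_base base of the concentration logarithm (default `exp(1)`).
#' @return a `macc_track`: the bin grid plus one score per bin.
#' @export
compute_macc <- function(tc, log_base = exp(1)) {
  stopifnot(inherits(tc, "titration_counts"))
  if (!tc$normalized) stop("compute_macc requires library-normalized counts")
  if (length(unique(tc$concentrations)) < 2) {
    stop("at least two distinct concentrations are required")
  }
  x <- -log(tc$concentrations, base = log_base)
  xc <- x - mean(x)
  slope <- as.numeric(tc$counts %*% xc) / sum(xc^2)
  macc_track(tc$bins, slope, gc_corrected = FALSE,
             n_concentrations = length(x), log_base = log_base,
             condition = tc$condition, replicate = tc$replicate)
}

#' Construct an accessibility track
#'
#' @param bins bin grid.
#' @param score numeric score per bin.
#' @param gc_corrected,n_concentrations,log_base,condition,replicate metadata.
#' @return a `macc_track` object.
#' @export
macc_track <- function(bins, score, gc_corrected = FALSE,
                       n_concentrations = NA_integer_, log_base = exp(1),
                       condition = NA_character_, replicate = NA_integer_) {
  if (length(score) != nrow(bins)) stop("one score per bin required")
  structure(list(bins = bins, score = as.numeric(score),
                 gc_corrected = isTRUE(gc_corrected),
                 n_concentrations = n_concentrations, log_base = log_base,
                 condition = condition, replicate = replicate),
            class = "macc_track")
}

#' GC-content correction of accessibility scores
#'
#' MNase digestion efficiency and library preparation introduce a smooth
#' dependence of the raw score on bin GC content. The expected score as a
#' function of GC is estimated by local regression (lowess, span
#' `span`) over all scored bins; the corrected score is
#' `raw - fitted(gc) + mean(raw)`, so the genome-wide mean is preserved.
#' Bins without GC annotation pass through unchanged and are flagged in the
#' `gc_missing` field.
#'
#' @param track a `macc_track` whose bins carry GC content.
#' @param span lowess smoother span (default 0.3).
#' @return the corrected `macc_track` (`gc_corrected = TRUE`).
#' @export
gc_correct <- function(track, span = 0.3) {
  stopifnot(inherits(track, "macc_track"))
  gc <- track$bins$gc
  ok <- is.finite(gc) & is.finite(track$score)
  if (sum(ok) < 100) {
    warning("fewer than 100 bins with GC content; correction not applied")
    return(track)
  }
  lw <- stats::lowess(gc[ok], track$score[ok], f = span)
  fitted <- stats::approx(lw$x, lw$y, xout = gc[ok], rule = 2,
                          ties = "ordered")$y
  track$score[ok] <- track$score[ok] - fitted + mean(track$score[ok])
  track$gc_corrected <- TRUE
  track$gc_missing <- !ok
  track
}

#' Median-shift a track to zero
#'
#' Validation transform: subtracts the genome-wide median so each sample is
#' centered independently before cross-sample comparison. Per-bin
#' differences between two tracks are unchanged up to a constant.
#'
#' @param track a `macc_track`.
#' @return the shifted track.
#' @export
median_shift <- function(track) {
  stopifnot(inherits(track, "macc_track"))
  track$score <- track$score - stats::median(track$score, na.rm = TRUE)
  track$median_shifted <- TRUE
  track
}

#' Average replicate tracks
#'
#' @param tracks list of `macc_track` objects on one grid.
#' @return a `macc_track` with the per-bin mean score.
#' @export
mean_track <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  for (t in tracks[-1]) {
    if (!same_grid(tracks[[1]]$bins, t$bins)) stop("bin grids differ")
  }
  sc <- rowMeans(do.call(cbind, lapply(tracks, `[[`, "score")))
  out <- tracks[[1]]
  out$score <- sc
  out$replicate <- NA_integer_
  out
}

#' @export
print.macc_track <- function(x, ...) {
  cat(sprintf("accessibility track: %d bins%s%s\n", length(x$score),
              if (x$gc_corrected) ", GC-corrected" else "",
              if (isTRUE(x$median_shifted)) ", median-shifted" else ""))
  cat(sprintf("  condition=%s replicate=%s score range [%.3g, %.3g]\n",
              x$condition, x$replicate,
              min(x$score, na.rm = TRUE), max(x$score, na.rm = TRUE)))
  invisible(x)
}
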