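# Anchor-relative averaging: site profiles with confidence bands, scaled
# metagene profiles, heatmap matrices and score-based splits.

# Running mean with window w (odd); partial windows at the edges.
running_mean <- function(x, w) {
  w <- as.integer(w)
  if (w <= 1L) return(x)
  n <- length(x)
  half <- w %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Interpolate track values (anchored at bin centers) at arbitrary genomic
# positions, one chromosome at a time. Positions beyond the outermost bin
# centers take the nearest center's value.
interpolate_track <- function(track, chrom, pos) {
  out <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    idx <- which(track$bins$chrom == ch)
    if (!length(idx)) stop("track has no bins on chromosome ", ch)
    centers <- (track$bins$start[idx] + track$bins$end[idx]) / 2
    sel <- chrom == ch
    out[sel] <- stats::approx(centers, track$score[idx], xout = pos[sel],
                              rule = 2, ties = "ordered")$y
  }
  out
}

profile_from_matrix <- function(M, offsets, smooth_w, signal, n_dropped,
                                extra = list()) {
  n <- nrow(M)
  mu <- colMeans(M)
  sdv <- if (n > 1) {
    sqrt(pmax(colMeans(M^2) - mu^2, 0) * n / (n - 1))
  } else rep(0, ncol(M))
  ci <- 1.96 * sdv / sqrt(n)
  out <- data.frame(offset = offsets,
                    mean = running_mean(mu, smooth_w),
                    ci_low = running_mean(mu - ci, smooth_w),
                    ci_high = running_mean(mu + ci, smooth_w))
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  structure(out, n_sites = n, n_dropped = n_dropped, signal = signal,
            smooth_window = smooth_w, class = c("macc_profile",
                                                "data.frame"))
}

#' Average signal profile around anchor sites
#'
#' Computes the signal at a grid of offsets around each anchor by linear
#' interpolation between bin-center values, averages over sites, applies a
#' short running-window smoothing, and attaches the pointwise 95%
#' confidence band (normal approximation across sites,
#' mean +/- 1.96 sd/sqrt(n)). Anchors whose flank extends past a chromosome
#' end are dropped (count recorded); minus-strand anchors are flipped so
#' positive offsets point downstream.
#'
#' @param track a `macc_track` (or any list with `bins` and `score`).
#' @param anchors data.frame with `chrom`, `pos` and optionally `strand`.
#' @param flank_bp half-width of the window.
#' @param step offset grid spacing in bp (default 10).
#' @param smooth_bp running smoothing window in bp (default 10).
#' @return a `macc_profile` data.frame (offset, mean, ci_low, ci_high) with
#'   attributes `n_sites`, `n_dropped`, `smooth_window`.
#' @export
site_profile <- function(track, anchors, flank_bp = 500, step = 10,
                         smooth_bp = 10) {
  sizes <- attr(track$bins, "chrom_sizes")
  keep <- anchors$pos - flank_bp >= 0 &
    anchors$pos + flank_bp <= sizes[anchors$chrom]
  n_dropped <- sum(!keep)
  a <- anchors[keep, , drop = FALSE]
  if (!nrow(a)) stop("no anchors remain after edge filtering")
  offsets <- seq(-flank_bp, flank_bp, by = step)
  xout <- rep(a$pos, each = length(offsets)) + offsets
  vals <- interpolate_track(track, rep(a$chrom, each = length(offsets)),
                            xout)
  M <- matrix(vals, nrow = nrow(a), ncol = length(offsets), byrow = TRUE)
  if (!is.null(a$strand)) {
    neg <- which(a$strand == "-")
    if (length(neg)) M[neg, ] <- M[neg, rev(seq_len(ncol(M))), drop = FALSE]
  }
  w <- max(1L, round(smooth_bp / step))
  if (w %% 2L == 0L) w <- w + 1L
  profile_from_matrix(M, offsets, w, signal = "MACC",
                      n_dropped = n_dropped)
}

# Per-gene row of body (scaled) and fixed-bp flank signal in
# transcriptional (5'->3') order.
gene_row_positions <- function(gene, n_body_bins, flank_bp, step) {
  s <- gene$start; e <- gene$end
  body <- s + (e - s) * (seq_len(n_body_bins) - 0.5) / n_body_bins
  m <- if (flank_bp >= step) seq(step, flank_bp, by = step) else numeric(0)
  if (gene$strand == "+") {
    c(s - rev(m), body, (e - 1) + m)
  } else {
    c((e - 1) + rev(m), rev(body), s - m)
  }
}

#' Scaled metagene profile across gene bodies
#'
#' Each gene body is rescaled to `n_body_bins` interpolated positions;
#' flanks are kept in fixed bp. Averaging, confidence band and smoothing
#' follow [site_profile()]; minus-strand genes are traversed 5' to 3'.
#'
#' @param track a `macc_track`.
#' @param genes data.frame (chrom, start, end, strand, id).
#' @param n_body_bins body resolution (default 100 positions).
#' @param flank_bp fixed flank on each side (default 500; 0 for body only).
#' @param step,smooth_bp flank grid spacing and smoothing, as in
#'   [site_profile()].
#' @return a `macc_profile` with a `region` column
#'   (upstream / body / downstream); body offsets are 1..n_body_bins, flank
#'   offsets are bp from the gene edge.
#' @export
metagene_profile <- function(track, genes, n_body_bins = 100,
                             flank_bp = 500, step = 10, smooth_bp = 10) {
  sizes <- attr(track$bins, "chrom_sizes")
  ok <- (genes$end - genes$start) >= n_body_bins &
    genes$start - flank_bp >= 0 &
    genes$end + flank_bp <= sizes[genes$chrom]
  if (!any(ok)) stop("no genes long enough for the requested scaling")
  g <- genes[ok, , drop = FALSE]
  m <- if (flank_bp >= step) length(seq(step, flank_bp, by = step)) else 0L
  rows <- t(vapply(seq_len(nrow(g)), function(i) {
    pos <- gene_row_positions(g[i, ], n_body_bins, flank_bp, step)
    interpolate_track(track, rep(g$chrom[i], length(pos)), pos)
  }, numeric(n_body_bins + 2L * m)))
  offsets <- c(if (m) seq(-flank_bp, -step, by = step),
               seq_len(n_body_bins),
               if (m) seq(step, flank_bp, by = step))
  region <- c(rep("upstream", m), rep("body", n_body_bins),
              rep("downstream", m))
  w <- max(1L, round(smooth_bp / step))
  if (w %% 2L == 0L) w <- w + 1L
  profile_from_matrix(rows, offsets, w, signal = "MACC",
                      n_dropped = sum(!ok),
                      extra = list(region = region))
}

#' Gene-by-position heatmap matrix of scaled body signal
#'
#' One row per gene (scaled to `n_body_bins` positions, strand-aware, no
#' smoothing), sorted by an ordering key. Ties keep the stable input
#' order. For difference tracks order by the signed per-gene change
#' ascending, so the strongest decreases come first; for occupancy order
#' descending.
#'
#' @param track a `macc_track` (signal or per-bin difference).
#' @param genes gene data.frame; rownames of the result are `genes$id`.
#' @param order_key numeric ordering key, one per gene (NA not allowed).
#' @param decreasing sort direction (default `FALSE`, i.e. ascending).
#' @param n_body_bins body resolution.
#' @return numeric matrix with attribute `order_key` (sorted key values).
#' @export
heatmap_matrix <- function(track, genes, order_key, decreasing = FALSE,
                           n_body_bins = 100) {
  stopifnot(length(order_key) == nrow(genes))
  if (anyNA(order_key)) {
    stop("missing ordering key for: ",
         paste(genes$id[is.na(order_key)], collapse = ", "))
  }
  rows <- t(vapply(seq_len(nrow(genes)), function(i) {
    pos <- gene_row_positions(genes[i, ], n_body_bins, 0, 10)
    interpolate_track(track, rep(genes$chrom[i], length(pos)), pos)
  }, numeric(n_body_bins)))
  rownames(rows) <- genes$id
  ord <- order(order_key, decreasing = decreasing, method = "radix")
  out <- rows[ord, , drop = FALSE]
  attr(out, "order_key") <- order_key[ord]
  out
}

#' Split items into score halves or quartiles
#'
#' Boundaries use type-7 (linear interpolation) quantiles; items whose
#' score ties a boundary stay with the lower group. Halves label the top
#' 50% `high`; quartiles run Q1 (lowest) to Q4 (highest).
#'
#' @param scores numeric scores (ties allowed).
#' @param mode `"halves"` or `"quartiles"`.
#' @return factor of group labels aligned with `scores`.
#' @export
split_by_score <- function(scores, mode = c("halves", "quartiles")) {
  mode <- match.arg(mode)
  if (!length(scores)) stop("empty input")
  if (length(unique(scores)) == 1L) {
    warning("all scores equal; a single degenerate group returned")
    lab <- if (mode == "halves") "low" else "Q1"
    return(factor(rep(lab, length(scores)),
                  levels = if (mode == "halves") c("low", "high") else
                    paste0("Q", 1:4)))
  }
  if (mode == "halves") {
    b <- stats::quantile(scores, 0.5, type = 7, names = FALSE)
    factor(ifelse(scores <= b, "low", "high"), levels = c("low", "high"))
  } else {
    b <- stats::quantile(scores, c(0.25, 0.5, 0.75), type = 7,
                         names = FALSE)
    cut(scores, breaks = c(-Inf, b, Inf), labels = paste0("Q", 1:4),
        right = TRUE)
  }
}

#' Per-concentration read-frequency profiles around anchors
#'
#' Builds one site profile per MNase concentration from normalized
#' frequencies (intended for counts built with the mononucleosome size
#' window, ~140-160 bp). The lowest-concentration profile reflects the
#' most accessible chromatin and is flagged as such.
#'
#' @param tc a normalized `titration_counts`.
#' @param anchors,flank_bp,step,smooth_bp as in [site_profile()].
#' @return named list of `macc_profile`s (one per concentration) with
#'   attribute `accessible_view` naming the lowest concentration.
#' @export
read_frequency_profile <- function(tc, anchors, flank_bp = 1000, step = 10,
                                   smooth_bp = 10) {
  stopifnot(inherits(tc, "titration_counts"))
  if (!tc$normalized) stop("normalized counts required")
  profs <- lapply(seq_along(tc$concentrations), function(j) {
    tr <- macc_track(tc$bins, tc$counts[, j],
                     condition = tc$condition, replicate = tc$replicate)
    p <- site_profile(tr, anchors, flank_bp = flank_bp, step = step,
                      smooth_bp = smooth_bp)
    attr(p, "signal") <- "read_frequency"
    attr(p, "concentration") <- tc$concentrations[j]
    p
  })
  names(profs) <- as.character(tc$concentrations)
  attr(profs, "accessible_view") <-
    as.character(min(tc$concentrations))
  profs
}

#' @export
print.macc_profile <- function(x, ...) {
  cat(sprintf("profile: %d offsets, %d sites (%d dropped), signal=%s\n",
              nrow(x), attr(x, "n_sites"), attr(x, "n_dropped"),
              attr(x, "signal")))
  invisible(x)
}
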