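# Differential accessibility between conditions: per-bin delta and
# moderated significance, feature classification, chromosome-level
# distribution statistics and randomized-site controls.

#' Per-bin accessibility difference
#'
#' @param rnai,control `macc_track` objects on identical bin grids.
#' @return data.frame (chrom, start, end, delta) with delta = rnai - control.
#' @export
delta_macc <- function(rnai, control) {
  stopifnot(inherits(rnai, "macc_track"), inherits(control, "macc_track"))
  if (!same_grid(rnai$bins, control$bins)) {
    stop("bin grids of the two tracks differ")
  }
  out <- data.frame(chrom = rnai$bins$chrom, start = rnai$bins$start,
                    end = rnai$bins$end,
                    delta = rnai$score - control$score,
                    stringsAsFactors = FALSE)
  attr(out, "bins") <- rnai$bins
  out
}

# Inverse of the trigamma function by Newton iteration.
trigamma_inverse <- function(y) {
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  x
}

# Empirical-Bayes moderated two-sample t test, row-wise.
#
# Row variances are pooled within groups (df d = n1 + n2 - 2) and shrunk
# toward a common prior variance s0^2 with prior df d0; both hyperparameters
# are estimated from the spread of log sample variances by the
# method of moments (var(log s^2) ~ trigamma(d/2) + trigamma(d0/2)).
# Two-sided p-values use the t distribution with d + d0 df.
moderated_t <- function(m1, m2) {
  n1 <- ncol(m1); n2 <- ncol(m2)
  if (n1 < 2 || n2 < 2) {
    stop("at least two replicates per condition are required")
  }
  mean1 <- rowMeans(m1); mean2 <- rowMeans(m2)
  d <- n1 + n2 - 2
  ss <- rowSums((m1 - mean1)^2) + rowSums((m2 - mean2)^2)
  s2 <- ss / d
  delta <- mean2 - mean1

  pos <- s2 > 0
  if (sum(pos) < 2) {
    t <- ifelse(delta == 0, 0, Inf * sign(delta))
    return(data.frame(delta = delta, t = t,
                      p_value = ifelse(delta == 0, 1, 0),
                      df_total = d))
  }
  e <- log(s2[pos])
  evar <- stats::var(e) - trigamma(d / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(mean(e) - digamma(d / 2) + log(d / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(mean(e) - digamma(d / 2) + log(d / 2))
  }
  s2_tilde <- if (is.finite(d0)) (d0 * s02 + d * s2) / (d0 + d) else
    rep(s02, length(s2))
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  t <- ifelse(se > 0, delta / se, ifelse(delta == 0, 0, Inf * sign(delta)))
  p <- 2 * stats::pt(-abs(t), df = d + d0)
  out <- data.frame(delta = delta, t = t, p_value = p, df_total = d + d0)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}

#' Moderated per-bin significance of accessibility change
#'
#' Tests each bin for a difference in accessibility between replicate score
#' tracks of two conditions using a moderated two-sample t statistic:
#' per-bin pooled variances are shrunk toward the genome-wide mean variance
#' by an empirical-Bayes weight whose prior df is estimated from the spread
#' of log variances, and p-values use the t distribution with augmented df.
#'
#' @param control_reps,rnai_reps lists of `macc_track` replicates (>= 2
#'   each) on a shared grid, or numeric matrices (bins x replicates).
#' @return data.frame (chrom, start, end, delta, t, p_value, fdr) where
#'   delta is rnai - control and fdr is the Benjamini-Hochberg adjusted
#'   p-value (informational; headline thresholds use raw p).
#' @export
test_bins <- function(control_reps, rnai_reps) {
  to_mat <- function(reps) {
    if (is.matrix(reps)) return(list(mat = reps, bins = NULL))
    stopifnot(is.list(reps), length(reps) >= 1)
    for (t in reps) stopifnot(inherits(t, "macc_track"))
    for (t in reps[-1]) {
      if (!same_grid(reps[[1]]$bins, t$bins)) stop("bin grids differ")
    }
    list(mat = do.call(cbind, lapply(reps, `[[`, "score")),
         bins = reps[[1]]$bins)
  }
  ctl <- to_mat(control_reps)
  rna <- to_mat(rnai_reps)
  if (!is.null(ctl$bins) && !is.null(rna$bins) &&
      !same_grid(ctl$bins, rna$bins)) {
    stop("bin grids of the two conditions differ")
  }
  res <- moderated_t(ctl$mat, rna$mat)
  d0 <- attr(res, "d0")
  res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  bins <- ctl$bins
  if (!is.null(bins)) {
    res <- cbind(data.frame(chrom = bins$chrom, start = bins$start,
                            end = bins$end, stringsAsFactors = FALSE), res)
    attr(res, "bins") <- bins
  }
  attr(res, "d0") <- d0
  attr(res, "design") <- sprintf(
    "moderated two-sample t, %d vs %d replicates, prior df %.3g",
    ncol(ctl$mat), ncol(rna$mat), d0 %||% NA_real_)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

gr0 <- function(chrom, start, end) {
  keep <- end > start
  GenomicRanges::GRanges(chrom[keep],
                         IRanges::IRanges(start[keep] + 1L, end[keep]))
}

#' Classify bins by genomic feature
#'
#' Assigns each bin (by its midpoint) to one of four exhaustive, exclusive
#' categories with precedence tss_tts > enhancer > gene_body > unannotated:
#' * `tss_tts`: within `tss_flank` bp upstream of a gene start or
#'   downstream of a gene end (strand-aware);
#' * `enhancer`: within `enhancer_flank` bp of an enhancer center;
#' * `gene_body`: inside a gene;
#' * `unannotated`: none of the above.
#'
#' @param bins a bin grid (or any data.frame with chrom/start/end).
#' @param genes data.frame (chrom, start, end, strand).
#' @param enhancers data.frame (chrom, pos); optional.
#' @param tss_flank,enhancer_flank window half-widths in bp (default 500).
#' @return factor of categories, one per bin.
#' @export
classify_regions <- function(bins, genes, enhancers = NULL,
                             tss_flank = 500, enhancer_flank = 500) {
  if (any(genes$end < genes$start)) {
    stop("gene with end < start: ",
         genes$id[which(genes$end < genes$start)[1]] %||% "unnamed")
  }
  mids <- (bins$start + bins$end) %/% 2L
  pts <- GenomicRanges::GRanges(bins$chrom, IRanges::IRanges(mids + 1L,
                                                             mids + 1L))
  # upstream-of-start and downstream-of-end windows; for - strand genes the
  # 5' end sits at `end`, so the two windows swap roles but their union is
  # strand-symmetric.
  up <- gr0(genes$chrom, pmax(genes$start - tss_flank, 0L), genes$start)
  down <- gr0(genes$chrom, genes$end, genes$end + tss_flank)
  tsswin <- c(up, down)
  body <- gr0(genes$chrom, genes$start, genes$end)
  cat <- rep("unannotated", nrow(bins))
  if (!is.null(enhancers) && nrow(enhancers)) {
    enh <- gr0(enhancers$chrom, pmax(enhancers$pos - enhancer_flank, 0L),
               enhancers$pos + enhancer_flank)
    cat[IRanges::overlapsAny(pts, enh)] <- "enhancer"
  }
  cat[IRanges::overlapsAny(pts, body) & cat == "unannotated"] <- "gene_body"
  cat[IRanges::overlapsAny(pts, tsswin)] <- "tss_tts"
  factor(cat, levels = c("gene_body", "tss_tts", "enhancer", "unannotated"))
}

#' Count significant bins per feature category
#'
#' Tallies bins with p below `p_threshold` in each category. With
#' `normalize = TRUE` each count is divided by the fraction of the genome
#' covered by its category (merged, non-double-counted bp, honoring the
#' same precedence as [classify_regions()]); a zero-coverage category is
#' reported as `NA`, not infinite.
#'
#' @param diff a [test_bins()] result carrying `chrom`/`start`/`end`.
#' @param category factor from [classify_regions()] aligned with `diff`.
#' @param p_threshold significance cutoff on the raw p-value (default 0.01).
#' @param normalize divide counts by genome-fraction coverage.
#' @param genes,enhancers,chrom_sizes annotation needed when
#'   `normalize = TRUE`.
#' @param tss_flank,enhancer_flank as in [classify_regions()].
#' @return data.frame (category, n_significant, genome_fraction,
#'   normalized).
#' @export
category_counts <- function(diff, category, p_threshold = 0.01,
                            normalize = FALSE, genes = NULL,
                            enhancers = NULL, chrom_sizes = NULL,
                            tss_flank = 500, enhancer_flank = 500) {
  lev <- c("gene_body", "tss_tts", "enhancer", "unannotated")
  sig <- diff$p_value < p_threshold
  n <- table(factor(category, levels = lev)[sig])
  out <- data.frame(category = lev, n_significant = as.integer(n[lev]),
                    stringsAsFactors = FALSE)
  if (normalize) {
    if (is.null(genes) || is.null(chrom_sizes)) {
      stop("normalization requires genes and chrom_sizes")
    }
    sizes <- as_chrom_sizes(chrom_sizes)
    gsize <- sum(sizes)
    up <- gr0(genes$chrom, pmax(genes$start - tss_flank, 0L), genes$start)
    down <- gr0(genes$chrom, genes$end, genes$end + tss_flank)
    tss <- GenomicRanges::reduce(c(up, down))
    enh <- if (!is.null(enhancers) && nrow(enhancers)) {
      GenomicRanges::reduce(gr0(enhancers$chrom,
                                pmax(enhancers$pos - enhancer_flank, 0L),
                                enhancers$pos + enhancer_flank))
    } else GenomicRanges::GRanges()
    body <- GenomicRanges::reduce(gr0(genes$chrom, genes$start, genes$end))
    enh_x <- GenomicRanges::setdiff(enh, tss)
    body_x <- GenomicRanges::setdiff(GenomicRanges::setdiff(body, tss), enh)
    bp <- c(gene_body = sum(GenomicRanges::width(body_x)),
            tss_tts = sum(GenomicRanges::width(tss)),
            enhancer = sum(GenomicRanges::width(enh_x)))
    bp["unannotated"] <- gsize - sum(bp)
    frac <- bp[lev] / gsize
    out$genome_fraction <- as.numeric(frac)
    out$normalized <- ifelse(frac > 0, out$n_significant / frac, NA_real_)
  }
  out
}

#' Chromosome-group distribution of accessibility scores
#'
#' Summarizes score distributions for the X chromosome, the autosomes and
#' all bins of each condition: n, median, quartiles (linear-interpolation
#' type 7) and the boxplot notch half-width 1.58 * IQR / sqrt(n)
#' (approximate 95% CI of the median). Two-sided Mann-Whitney tests compare
#' X vs autosomes within each condition and condition pairs within each
#' group.
#'
#' @param tracks named list of `macc_track`s, one per condition.
#' @param x_name X chromosome name.
#' @return list with `summary` and `tests` data.frames.
#' @export
chromosome_distribution <- function(tracks, x_name) {
  stopifnot(length(tracks) >= 1, !is.null(names(tracks)))
  pull <- function(tr, grp) {
    on_x <- tr$bins$chrom == x_name
    switch(grp, X = tr$score[on_x], autosomes = tr$score[!on_x],
           all = tr$score)
  }
  groups <- c("X", "autosomes", "all")
  rows <- list(); tests <- list()
  for (cond in names(tracks)) {
    for (grp in groups) {
      v <- pull(tracks[[cond]], grp)
      if (!length(v)) stop("empty group: ", grp, " in ", cond)
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, group = grp, n = length(v), median = q[2],
        q25 = q[1], q75 = q[3],
        notch = 1.58 * (q[3] - q[1]) / sqrt(length(v)),
        stringsAsFactors = FALSE)
    }
    p <- stats::wilcox.test(pull(tracks[[cond]], "X"),
                            pull(tracks[[cond]], "autosomes"),
                            exact = FALSE)$p.value
    tests[[length(tests) + 1L]] <- data.frame(
      comparison = "X_vs_autosomes", condition = cond, group = NA, p = p,
      stringsAsFactors = FALSE)
  }
  if (length(tracks) >= 2) {
    prs <- utils::combn(names(tracks), 2, simplify = FALSE)
    for (pr in prs) {
      for (grp in groups) {
        p <- stats::wilcox.test(pull(tracks[[pr[1]]], grp),
                                pull(tracks[[pr[2]]], grp),
                                exact = FALSE)$p.value
        tests[[length(tests) + 1L]] <- data.frame(
          comparison = paste(pr, collapse = "_vs_"), condition = NA,
          group = grp, p = p, stringsAsFactors = FALSE)
      }
    }
  }
  list(summary = do.call(rbind, rows), tests = do.call(rbind, tests),
       notch_convention = "1.58*IQR/sqrt(n), type-7 quartiles")
}

#' Mean accessibility change per gene body
#'
#' @param delta a [delta_macc()] result.
#' @param genes gene data.frame (chrom, start, end, id).
#' @return named numeric vector: mean delta over bins whose midpoint falls
#'   inside each gene body (NA when a gene covers no bin).
#' @export
gene_deltas <- function(delta, genes) {
  mids <- (delta$start + delta$end) %/% 2L
  pts <- GenomicRanges::GRanges(delta$chrom,
                                IRanges::IRanges(mids + 1L, mids + 1L))
  body <- gr0(genes$chrom, genes$start, genes$end)
  hits <- GenomicRanges::findOverlaps(pts, body)
  keep <- genes$end > genes$start
  gid <- genes$id[keep][S4Vectors::subjectHits(hits)]
  means <- tapply(delta$delta[S4Vectors::queryHits(hits)], gid, mean)
  out <- stats::setNames(rep(NA_real_, nrow(genes)), genes$id)
  out[names(means)] <- as.numeric(means)
  out
}

#' Fractions of genes losing or gaining accessibility
#'
#' @param gene_delta one summary delta per gene (e.g. [gene_deltas()]).
#' @return list: `percent_decrease`, `percent_increase` (over genes with
#'   nonzero delta), `n_zero`, `n`.
#' @export
direction_fractions <- function(gene_delta) {
  gene_delta <- gene_delta[!is.na(gene_delta)]
  if (!length(gene_delta)) stop("empty gene set")
  nz <- gene_delta != 0
  if (!any(nz)) {
    warning("all gene deltas are zero")
    return(list(percent_decrease = NA_real_, percent_increase = NA_real_,
                n_zero = length(gene_delta), n = length(gene_delta)))
  }
  list(percent_decrease = 100 * sum(gene_delta < 0) / sum(nz),
       percent_increase = 100 * sum(gene_delta > 0) / sum(nz),
       n_zero = sum(!nz), n = length(gene_delta))
}

#' Random genomic positions outside a repeat mask
#'
#' Uniformly samples `n` positions over the unmasked genome by rejection;
#' used as a randomized control anchor set.
#'
#' @param n number of sites.
#' @param chrom_sizes chromosome lengths (any form accepted by
#'   [bin_genome()]).
#' @param repeat_mask data.frame (chrom, start, end) of excluded intervals.
#' @param seed integer seed; fixed seed gives identical sets.
#' @return data.frame (chrom, pos).
#' @export
randomized_sites <- function(n, chrom_sizes, repeat_mask = NULL, seed = 1L) {
  sizes <- as_chrom_sizes(chrom_sizes)
  masked_bp <- 0
  if (!is.null(repeat_mask) && nrow(repeat_mask)) {
    red <- GenomicRanges::reduce(gr0(repeat_mask$chrom, repeat_mask$start,
                                     repeat_mask$end))
    masked_bp <- sum(GenomicRanges::width(red))
  }
  if (masked_bp >= sum(sizes)) stop("repeat mask covers the whole genome")
  set.seed(seed)
  out_chrom <- character(0); out_pos <- numeric(0)
  while (length(out_pos) < n) {
    m <- 2L * (n - length(out_pos)) + 10L
    ch <- sample(names(sizes), m, replace = TRUE, prob = sizes)
    pos <- floor(stats::runif(m) * sizes[ch])
    ok <- rep(TRUE, m)
    if (!is.null(repeat_mask) && nrow(repeat_mask)) {
      pts <- GenomicRanges::GRanges(ch, IRanges::IRanges(pos + 1, pos + 1))
      ok <- !IRanges::overlapsAny(pts, gr0(repeat_mask$chrom,
                                           repeat_mask$start,
                                           repeat_mask$end))
    }
    out_chrom <- c(out_chrom, ch[ok])
    out_pos <- c(out_pos, pos[ok])
  }
  data.frame(chrom = out_chrom[seq_len(n)], pos = out_pos[seq_len(n)],
             stringsAsFactors = FALSE)
}
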