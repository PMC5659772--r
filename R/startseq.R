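# Nascent-transcription (Start-seq) analysis: observed TSS definition,
# differential Start-RNA abundance and per-chromosome regulation summaries.

#' Define observed TSS from 5'-end read signal
#'
#' For each gene, the observed TSS is the position with the maximum summed
#' 5'-end signal on the gene's strand within +/- `window_bp` of the
#' annotated start; ties take the lower coordinate, and genes with zero
#' signal in the window are excluded. This is a simplified argmax
#' definition and is flagged as non-canonical in the result metadata.
#'
#' @param reads data.frame of stranded 5'-end read positions (`chrom`,
#'   `pos`, `strand`).
#' @param genes gene data.frame (chrom, start, end, strand, id).
#' @param window_bp search half-width (default 250).
#' @return data.frame (gene_id, chrom, obs_tss, strand, signal).
#' @export
define_obstss <- function(reads, genes, window_bp = 250) {
  if (is.null(reads$strand) || !nrow(reads)) {
    stop("stranded 5'-end read positions are required")
  }
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    astart <- if (g$strand == "+") g$start else g$end - 1L
    sel <- reads$chrom == g$chrom & reads$strand == g$strand &
      reads$pos >= astart - window_bp & reads$pos <= astart + window_bp
    if (!any(sel)) return(NULL)
    tab <- table(reads$pos[sel])
    best <- max(tab)
    pos <- min(as.integer(names(tab)[tab == best]))
    data.frame(gene_id = g$id, chrom = g$chrom, obs_tss = pos,
               strand = g$strand, signal = as.integer(best),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), chrom = character(0),
                      obs_tss = integer(0), strand = character(0),
                      signal = integer(0))
  }
  attr(out, "definition") <- sprintf(
    "argmax of 5'-end signal within +/-%d bp of annotated start (non-canonical simplification)",
    window_bp)
  out
}

#' Differential Start-RNA abundance per observed TSS
#'
#' Counts are normalized to counts-per-million per replicate, transformed
#' as log2(cpm + 1), and tested with the same moderated two-sample t
#' statistic used for accessibility bins. Positive regulation means the
#' abundance decreases after RNAi (the factor normally promotes
#' transcription there); negative regulation means it increases. TSS with
#' zero counts in every sample are excluded and logged.
#'
#' @param counts integer matrix, TSS x samples; rownames identify TSS.
#' @param condition character/factor of column conditions with exactly two
#'   levels, control first.
#' @param alpha significance threshold on the raw p-value (default 0.05).
#' @return data.frame (id, chrom?, mean_control, mean_rnai, delta_log2,
#'   p_value, fdr, direction) with attribute `n_excluded`.
#' @export
differential_start <- function(counts, condition, alpha = 0.05) {
  counts <- as.matrix(counts)
  # first level = first condition seen (control), not alphabetical
  condition <- factor(condition, levels = unique(as.character(condition)))
  stopifnot(length(condition) == ncol(counts))
  if (nlevels(condition) != 2) stop("exactly two conditions required")
  if (any(table(condition) < 2)) {
    stop("at least two replicates per condition are required")
  }
  keep <- rowSums(counts) > 0
  n_excluded <- sum(!keep)
  m <- counts[keep, , drop = FALSE]
  cpm <- sweep(m, 2, 1e6 / colSums(m), `*`)
  lg <- log2(cpm + 1)
  ctl <- lg[, condition == levels(condition)[1], drop = FALSE]
  rna <- lg[, condition == levels(condition)[2], drop = FALSE]
  res <- moderated_t(ctl, rna)
  out <- data.frame(id = rownames(m) %||% as.character(which(keep)),
                    mean_control = rowMeans(ctl), mean_rnai = rowMeans(rna),
                    delta_log2 = res$delta, p_value = res$p_value,
                    fdr = stats::p.adjust(res$p_value, "BH"),
                    stringsAsFactors = FALSE)
  out$direction <- ifelse(out$p_value >= alpha | out$delta_log2 == 0,
                          "unchanged",
                          ifelse(out$delta_log2 < 0, "positive_regulation",
                                 "negative_regulation"))
  attr(out, "alpha") <- alpha
  attr(out, "n_excluded") <- n_excluded
  attr(out, "normalization") <-
    "cpm per replicate, log2(cpm+1) (stand-in; original not stated)"
  out
}

#' Per-chromosome regulation summary
#'
#' Percentage of significantly changed TSS per chromosome, for X vs
#' autosomes and overall, with the split of significant TSS into positive
#' regulation (abundance down after RNAi) and negative regulation
#' (abundance up). Percentages are rounded to one decimal.
#'
#' @param tested a [differential_start()] result with a `chrom` column, or
#'   any data.frame with `chrom`, `p_value` and `direction`.
#' @param x_name X chromosome name (for the X/autosome grouping); `NULL`
#'   skips it.
#' @param alpha significance threshold; defaults to the one used in
#'   testing.
#' @return data.frame (group, n_total, n_significant, pct_changed,
#'   pct_positive, pct_negative). Direction percentages are `NA` when no
#'   TSS is significant.
#' @export
regulation_summary <- function(tested, x_name = NULL,
                               alpha = attr(tested, "alpha") %||% 0.05) {
  stopifnot(all(c("chrom", "p_value", "direction") %in% names(tested)))
  one <- function(df, label) {
    sig <- df$p_value < alpha
    n_sig <- sum(sig)
    pos <- sum(sig & df$direction == "positive_regulation")
    neg <- sum(sig & df$direction == "negative_regulation")
    data.frame(group = label, n_total = nrow(df), n_significant = n_sig,
               pct_changed = round(100 * n_sig / nrow(df), 1),
               pct_positive = if (n_sig) round(100 * pos / n_sig, 1) else
                 NA_real_,
               pct_negative = if (n_sig) round(100 * neg / n_sig, 1) else
                 NA_real_,
               stringsAsFactors = FALSE)
  }
  parts <- lapply(split(tested, tested$chrom), function(df) {
    one(df, df$chrom[1])
  })
  out <- do.call(rbind, c(parts, list(one(tested, "all"))))
  if (!is.null(x_name)) {
    on_x <- tested$chrom == x_name
    if (any(on_x)) out <- rbind(out, one(tested[on_x, ], "X"))
    if (any(!on_x)) out <- rbind(out, one(tested[!on_x, ], "autosomes"))
  }
  rownames(out) <- NULL
  out
}

#' Expression quartiles from control counts
#'
#' Ranks TSS by mean control-replicate abundance and labels quartiles Q1
#' (lowest) to Q4 (highest) using the same quantile convention as
#' [split_by_score()].
#'
#' @param control_counts matrix (TSS x control replicates) or vector of
#'   mean counts.
#' @return factor of quartile labels.
#' @export
expression_quartiles <- function(control_counts) {
  v <- if (is.matrix(control_counts)) rowMeans(control_counts) else
    as.numeric(control_counts)
  split_by_score(v, mode = "quartiles")
}
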