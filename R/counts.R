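# Fragment counting, hotspot filtering and library normalization.

# Encode (chrom, pos) as a double; exact for pos < 2^32 and a few thousand
# chromosomes, so safe for any realistic genome handled here.
encode_pos <- function(chrom_idx, pos) chrom_idx * 2^32 + pos

#' Identify hotspot positions with abnormally high read counts
#'
#' Positions where an unusually large number of fragments start (PCR or
#' alignment artifacts) are flagged by a Z-score computed over all covered
#' positions of the sample: a position is masked when
#' (count - mean) / sd >= `z_threshold`. Fragments starting at masked
#' positions are discarded by [count_fragments()].
#'
#' @param fragments data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param z_threshold Z-score cutoff (default 7).
#' @return A `hotspot_mask` object: masked positions, the threshold, and the
#'   per-sample mean/sd of per-position start counts.
#' @export
filter_hotspots <- function(fragments, z_threshold = 7) {
  stopifnot(all(c("chrom", "start") %in% names(fragments)))
  chroms <- unique(fragments$chrom)
  code <- encode_pos(match(fragments$chrom, chroms), fragments$start)
  r <- rle(sort(code))
  m <- mean(r$lengths)
  s <- stats::sd(r$lengths)
  if (length(r$lengths) < 2 || is.na(s) || s == 0) {
    warning("per-position counts have zero spread; no positions masked")
    masked <- numeric(0)
  } else {
    z <- (r$lengths - m) / s
    masked <- r$values[z >= z_threshold]
  }
  pos_df <- data.frame(chrom = chroms[masked %/% 2^32],
                       pos = masked %% 2^32,
                       stringsAsFactors = FALSE)
  structure(list(positions = pos_df,
                 chrom_levels = chroms,
                 codes = masked,
                 z_threshold = z_threshold,
                 mean = m, sd = if (is.na(s)) 0 else s,
                 n_covered = length(r$lengths),
                 frac_masked = length(masked) / max(1L, length(r$lengths))),
            class = "hotspot_mask")
}

#' @export
print.hotspot_mask <- function(x, ...) {
  cat(sprintf(paste0("hotspot mask: %d of %d covered positions ",
                     "(%.3g%%) at Z >= %g\n"),
              nrow(x$positions), x$n_covered, 100 * x$frac_masked,
              x$z_threshold))
  invisible(x)
}

#' Count fragments per genomic bin
#'
#' Each fragment is assigned to exactly one bin by its midpoint. Fragments
#' whose length falls outside `size_range` (inclusive) or that start at a
#' masked hotspot position are dropped; the tallies are recorded as
#' attributes of the returned vector.
#'
#' @param fragments data.frame with `chrom`, `start`, `end`.
#' @param bins a [bin_genome()] grid.
#' @param size_range inclusive fragment-length window in bp. The default
#'   `c(100, 200)` targets the accessibility statistic; use `c(140, 160)`
#'   for mononucleosome read-frequency profiles.
#' @param mask optional `hotspot_mask` from [filter_hotspots()].
#' @return integer vector of counts, one per bin, with attributes
#'   `n_total`, `n_kept`, `n_dropped_size`, `n_dropped_mask`.
#' @export
count_fragments <- function(fragments, bins, size_range = c(100, 200),
                            mask = NULL) {
  sizes <- attr(bins, "chrom_sizes")
  ci <- match(fragments$chrom, names(sizes))
  if (anyNA(ci)) {
    bad <- which(is.na(ci))[1]
    stop(sprintf("fragment %d on unknown chromosome '%s'",
                 bad, fragments$chrom[bad]))
  }
  over <- which(fragments$end > sizes[ci] | fragments$start < 0)
  if (length(over)) {
    b <- over[1]
    stop(sprintf("fragment %d (%s:%d-%d) extends beyond chromosome bounds",
                 b, fragments$chrom[b], fragments$start[b], fragments$end[b]))
  }
  n_total <- nrow(fragments)
  len <- fragments$end - fragments$start
  keep <- len >= size_range[1] & len <= size_range[2]
  n_dropped_size <- sum(!keep)
  n_dropped_mask <- 0L
  if (!is.null(mask) && length(mask$codes)) {
    mci <- match(fragments$chrom, mask$chrom_levels)
    code <- encode_pos(mci, fragments$start)
    in_mask <- !is.na(mci) & code %in% mask$codes
    n_dropped_mask <- sum(keep & in_mask)
    keep <- keep & !in_mask
  }
  f <- fragments[keep, , drop = FALSE]
  mid <- (f$start + f$end) %/% 2L
  idx <- bin_lookup(bins, f$chrom, mid)
  counts <- tabulate(idx, nbins = nrow(bins))
  structure(counts, n_total = n_total, n_kept = sum(keep),
            n_dropped_size = n_dropped_size,
            n_dropped_mask = n_dropped_mask)
}

#' Construct a titration counts object
#'
#' Bundles per-bin counts across the MNase concentration series for one
#' sample (condition x replicate).
#'
#' @param bins a [bin_genome()] grid.
#' @param concentrations positive, distinct MNase concentrations (units),
#'   one per column of `counts`.
#' @param counts numeric matrix, bins x concentrations.
#' @param normalized whether columns are already counts-per-million.
#' @param condition,replicate,size_range sample metadata.
#' @return a `titration_counts` object.
#' @export
titration_counts <- function(bins, concentrations, counts,
                             normalized = FALSE, condition = NA_character_,
                             replicate = NA_integer_,
                             size_range = c(100, 200)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(bins)) {
    stop("counts rows must match the bin grid")
  }
  if (ncol(counts) != length(concentrations)) {
    stop("one counts column per concentration required")
  }
  if (any(concentrations <= 0) || anyDuplicated(concentrations)) {
    stop("concentrations must be positive and distinct")
  }
  colnames(counts) <- as.character(concentrations)
  structure(list(bins = bins, concentrations = as.numeric(concentrations),
                 counts = counts, normalized = isTRUE(normalized),
                 condition = condition, replicate = replicate,
                 size_range = size_range),
            class = "titration_counts")
}

#' Count a full titration series into bins
#'
#' Convenience wrapper running per-sample hotspot filtering and binning for
#' each concentration of a series.
#'
#' @param fragments_by_conc named list of fragment data.frames; names are
#'   the MNase concentrations.
#' @param bins bin grid.
#' @param size_range fragment-length window (see [count_fragments()]).
#' @param z_threshold hotspot Z cutoff; `NULL` disables filtering.
#' @param ... passed to [titration_counts()].
#' @return a raw (unnormalized) `titration_counts`.
#' @export
count_titration <- function(fragments_by_conc, bins,
                            size_range = c(100, 200), z_threshold = 7, ...) {
  conc <- as.numeric(names(fragments_by_conc))
  if (anyNA(conc)) stop("fragments_by_conc must be named by concentration")
  cols <- lapply(fragments_by_conc, function(fr) {
    mask <- if (is.null(z_threshold)) NULL else {
      suppressWarnings(filter_hotspots(fr, z_threshold))
    }
    count_fragments(fr, bins, size_range = size_range, mask = mask)
  })
  titration_counts(bins, conc, do.call(cbind, cols),
                   size_range = size_range, ...)
}

#' Library-size normalize a titration series
#'
#' Scales each concentration column to counts-per-million of its
#' post-filter total. Refuses to normalize twice.
#'
#' @param tc a raw `titration_counts`.
#' @return the same object with CPM columns and `normalized = TRUE`.
#' @export
normalize_library <- function(tc) {
  stopifnot(inherits(tc, "titration_counts"))
  if (tc$normalized) stop("titration counts are already normalized")
  totals <- colSums(tc$counts)
  if (any(totals == 0)) {
    stop("zero-total column(s) at concentration: ",
         paste(tc$concentrations[totals == 0], collapse = ", "))
  }
  tc$counts <- sweep(tc$counts, 2, 1e6 / totals, `*`)
  tc$normalized <- TRUE
  tc$library_sizes <- totals
  tc
}

#' Double X-linked reads and renormalize
#'
#' Validation recomputation compensating for the single X chromosome in
#' male cells relative to two copies of each autosome: raw counts in bins on
#' the X are doubled and the series is then library-size normalized.
#'
#' @param tc a raw (unnormalized) `titration_counts`.
#' @param x_name X chromosome name.
#' @return a normalized `titration_counts` with X counts doubled.
#' @export
double_x_reads <- function(tc, x_name) {
  stopifnot(inherits(tc, "titration_counts"))
  if (tc$normalized) stop("double_x_reads requires raw counts")
  sizes <- attr(tc$bins, "chrom_sizes")
  if (!x_name %in% names(sizes)) {
    stop("unknown chromosome name: ", x_name)
  }
  on_x <- tc$bins$chrom == x_name
  tc$counts[on_x, ] <- tc$counts[on_x, , drop = FALSE] * 2
  tc <- normalize_library(tc)
  tc$x_doubled <- x_name
  tc
}

#' @export
print.titration_counts <- function(x, ...) {
  cat(sprintf("titration counts: %d bins x %d concentrations (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(x$concentrations, collapse = ", ")))
  cat(sprintf("  %s; condition=%s replicate=%s\n",
              if (x$normalized) "normalized (CPM)" else "raw counts",
              x$condition, x$replicate))
  invisible(x)
}
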