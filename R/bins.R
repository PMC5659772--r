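# Genome binning and GC annotation.

#' Normalize a chromosome-sizes argument
#'
#' Accepts a named numeric vector, a data.frame with columns `chrom`/`size`
#' (or two unnamed columns), or the path of a two-column chrom.sizes TSV.
#'
#' @param chrom_sizes see description.
#' @return named numeric vector of chromosome lengths (bp).
#' @keywords internal
as_chrom_sizes <- function(chrom_sizes) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1L) {
    if (!file.exists(chrom_sizes)) {
      stop("chrom.sizes file not found: ", chrom_sizes)
    }
    df <- utils::read.table(chrom_sizes, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    sizes <- stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
  } else if (is.data.frame(chrom_sizes)) {
    cn <- if (all(c("chrom", "size") %in% names(chrom_sizes))) {
      c("chrom", "size")
    } else {
      names(chrom_sizes)[1:2]
    }
    sizes <- stats::setNames(as.numeric(chrom_sizes[[cn[2]]]),
                             as.character(chrom_sizes[[cn[1]]]))
  } else {
    sizes <- chrom_sizes
  }
  if (is.null(names(sizes)) || any(!nzchar(names(sizes)))) {
    stop("chromosome sizes must be named")
  }
  if (any(!is.finite(sizes)) || any(sizes <= 0)) {
    stop("chromosome sizes must be positive")
  }
  sizes
}

#' Tile a genome into fixed-width bins
#'
#' Produces the non-overlapping bin grid on which all accessibility scores
#' are computed. Bins are 0-based half-open and tile each chromosome in
#' order; the last bin of a chromosome may be shorter than `bin_size`.
#' When a genome sequence is supplied the per-bin GC fraction is attached
#' (computed over non-N bases; all-N bins get `NA`).
#'
#' @param chrom_sizes named vector of chromosome lengths, a data.frame with
#'   columns `chrom` and `size`, or the path of a chrom.sizes TSV.
#' @param bin_size bin width in bp (default 100).
#' @param fasta optional genome sequence: path to a FASTA file or a
#'   [Biostrings::DNAStringSet].
#' @return A `genome_bins` data.frame with columns `chrom`, `start`, `end`,
#'   `gc`, carrying `bin_size` and `chrom_sizes` attributes.
#' @examples
#' bin_genome(c(chr1 = 250), bin_size = 100)
#' @export
bin_genome <- function(chrom_sizes, bin_size = 100, fasta = NULL) {
  sizes <- as_chrom_sizes(chrom_sizes)
  if (bin_size < 1) stop("bin_size must be >= 1")

  pieces <- lapply(names(sizes), function(ch) {
    starts <- seq(0, sizes[[ch]] - 1, by = bin_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_size, sizes[[ch]]),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  bins$gc <- NA_real_

  if (!is.null(fasta)) {
    seqs <- if (inherits(fasta, "DNAStringSet")) {
      fasta
    } else {
      Biostrings::readDNAStringSet(fasta)
    }
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    missing_seq <- setdiff(names(sizes), names(seqs))
    if (length(missing_seq)) {
      stop("chromosomes absent from FASTA: ",
           paste(missing_seq, collapse = ", "))
    }
    bad_len <- names(sizes)[Biostrings::width(seqs[names(sizes)]) != sizes]
    if (length(bad_len)) {
      stop("FASTA/chrom.sizes length mismatch for: ",
           paste(bad_len, collapse = ", "))
    }
    for (ch in names(sizes)) {
      idx <- which(bins$chrom == ch)
      v <- Biostrings::Views(seqs[[ch]], start = bins$start[idx] + 1L,
                             end = bins$end[idx])
      f <- Biostrings::letterFrequency(v, letters = c("GC", "AT"))
      tot <- f[, 1] + f[, 2]
      gc <- f[, 1] / tot
      gc[tot == 0] <- NA_real_
      bins$gc[idx] <- gc
    }
  }

  structure(bins,
            bin_size = bin_size,
            chrom_sizes = sizes,
            class = c("genome_bins", "data.frame"))
}

# Map (chrom, pos) pairs to row indices of a genome_bins grid. Positions are
# 0-based; pos must lie in [0, size). Vectorized.
bin_lookup <- function(bins, chrom, pos) {
  sizes <- attr(bins, "chrom_sizes")
  bs <- attr(bins, "bin_size")
  nb <- ceiling(sizes / bs)
  offs <- stats::setNames(c(0, cumsum(nb))[seq_along(nb)], names(nb))
  ci <- match(chrom, names(sizes))
  if (anyNA(ci)) {
    stop("unknown chromosome(s): ",
         paste(unique(chrom[is.na(ci)]), collapse = ", "))
  }
  as.integer(offs[ci] + pos %/% bs + 1L)
}

bin_midpoints <- function(bins) (bins$start + bins$end) %/% 2L

same_grid <- function(a, b) {
  nrow(a) == nrow(b) && all(a$chrom == b$chrom) &&
    all(a$start == b$start) && all(a$end == b$end)
}

#' @export
print.genome_bins <- function(x, ...) {
  cat(sprintf("genome bins: %d bins of %d bp over %d chromosome(s)\n",
              nrow(x), attr(x, "bin_size"),
              length(attr(x, "chrom_sizes"))))
  cat(sprintf("GC content: %s\n",
              if (all(is.na(x$gc))) "absent" else "present"))
  invisible(x)
}
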