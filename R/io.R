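# Plain-text format readers/writers. Coordinates are 0-based half-open in
# memory and on disk (BED conventions); bedGraph is the native track
# format.

#' Read fragment intervals
#'
#' BED input yields one fragment per line; SAM/BAM input resolves properly
#' paired reads to the outer template span (leftmost mate position plus
#' TLEN). Orphan or improper pairs are skipped with a count recorded in
#' the `n_skipped` attribute.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"bed"`, `"sam"` or `"bam"`.
#' @return data.frame (chrom, start, end), sorted, 0-based half-open.
#' @export
read_fragments <- function(path, format = c("auto", "bed", "sam", "bam")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, bed = "bed", sam = "sam", bam = "bam",
                     stop("cannot infer format from extension: ", path))
  }
  if (format == "bed") {
    fr <- read_bed(path)[, c("chrom", "start", "end")]
  } else {
    bam <- path
    if (format == "sam") {
      bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                              indexDestination = FALSE)
    }
    p <- Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isProperPair = TRUE,
                                    isUnmappedQuery = FALSE),
      what = c("rname", "pos", "isize"))
    x <- Rsamtools::scanBam(bam, param = p)[[1]]
    keep <- !is.na(x$isize) & x$isize > 0
    n_all <- Rsamtools::countBam(bam)$records
    fr <- data.frame(chrom = as.character(x$rname[keep]),
                     start = x$pos[keep] - 1L,
                     end = x$pos[keep] - 1L + x$isize[keep],
                     stringsAsFactors = FALSE)
    attr(fr, "n_skipped") <- n_all - 2L * nrow(fr)
  }
  fr[order(fr$chrom, fr$start, method = "radix"), , drop = FALSE]
}

#' Read a BED file (3-6 columns)
#'
#' Validates coordinates per record and fails naming the offending line.
#'
#' @param path BED path (may be gzipped).
#' @return data.frame with chrom, start, end and, when present, name,
#'   score, strand.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          comment.char = "#", quote = "")
  if (ncol(df) < 3) stop("BED requires at least 3 columns: ", path)
  names(df)[1:3] <- c("chrom", "start", "end")
  extra <- c("name", "score", "strand")
  for (j in seq_len(min(3, ncol(df) - 3))) names(df)[3 + j] <- extra[j]
  if (!is.numeric(df$start) || !is.numeric(df$end)) {
    stop("non-numeric coordinates in ", path)
  }
  bad <- which(df$end <= df$start | df$start < 0)
  if (length(bad)) {
    stop(sprintf("invalid interval on line %d of %s: %s %s %s", bad[1],
                 path, df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]]))
  }
  df
}

#' Write fragments (or any intervals) as BED3
#'
#' @param fragments data.frame (chrom, start, end).
#' @param path output path; a `.gz` suffix gzips.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fragments, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(fragments[, c("chrom", "start", "end")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write an accessibility track as bedGraph
#'
#' Four columns (chrom, start, end, score) with scores printed to six
#' decimal places, so a write/read round trip is lossless at that
#' precision. Adjacent bins with equal printed scores can optionally be
#' merged.
#'
#' @param track a `macc_track`.
#' @param path output path.
#' @param merge_adjacent merge runs of equal-score contiguous bins.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, merge_adjacent = FALSE) {
  b <- track$bins
  # chromosomes must form contiguous blocks with increasing starts inside
  blocks <- rle(b$chrom)$values
  if (anyDuplicated(blocks) ||
      any(unlist(tapply(b$start, factor(b$chrom, levels = blocks),
                        is.unsorted, strictly = TRUE)))) {
    stop("track bins must be sorted by chromosome and start")
  }
  sc <- sprintf("%.6f", track$score)
  df <- data.frame(chrom = b$chrom, start = b$start, end = b$end,
                   score = sc, stringsAsFactors = FALSE)
  if (merge_adjacent && nrow(df)) {
    run <- cumsum(c(TRUE, df$chrom[-1] != df$chrom[-nrow(df)] |
                      df$score[-1] != df$score[-nrow(df)] |
                      df$start[-1] != df$end[-nrow(df)]))
    df <- data.frame(chrom = tapply(df$chrom, run, `[`, 1),
                     start = tapply(df$start, run, min),
                     end = tapply(df$end, run, max),
                     score = tapply(df$score, run, `[`, 1),
                     stringsAsFactors = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track type=bedGraph", con)
  if (nrow(df)) {
    writeLines(paste(df$chrom, df$start, df$end, df$score, sep = "\t"),
               con)
  }
  invisible(path)
}

#' Read a bedGraph track
#'
#' @param path bedGraph path; `track`/`browser` header lines are skipped.
#' @param chrom_sizes optional sizes to attach to the bin grid.
#' @return a `macc_track` (bins without GC annotation).
#' @export
read_bedgraph <- function(path, chrom_sizes = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (!length(lines)) {
    bins <- structure(data.frame(chrom = character(0), start = integer(0),
                                 end = integer(0), gc = numeric(0)),
                      bin_size = NA_integer_,
                      chrom_sizes = if (is.null(chrom_sizes)) numeric(0)
                                    else as_chrom_sizes(chrom_sizes),
                      class = c("genome_bins", "data.frame"))
    return(macc_track(bins, numeric(0)))
  }
  df <- utils::read.table(text = lines, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "score"))
  sizes <- if (is.null(chrom_sizes)) {
    tapply(df$end, df$chrom, max)[unique(df$chrom)]
  } else as_chrom_sizes(chrom_sizes)
  bins <- structure(data.frame(chrom = df$chrom, start = df$start,
                               end = df$end, gc = NA_real_,
                               stringsAsFactors = FALSE),
                    bin_size = max(df$end - df$start),
                    chrom_sizes = sizes,
                    class = c("genome_bins", "data.frame"))
  macc_track(bins, df$score)
}
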