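# Synthetic genome and data generator with known ground truth.
#
# The generator emulates the study design: a four-point MNase titration
# (1.5, 6.25, 25, 100 units), two replicates, and three RNAi conditions
# (control, clamp_rnai, msl2_rnai) on a scaled-down genome with one X
# chromosome and two autosomes. Per-bin accessibility is linear in
# -log(concentration) by construction, so the estimand of compute_macc()
# equals the stored true slope.

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator with defaults
#' matching the emulated study design. All randomness downstream flows from
#' `seed`.
#'
#' @param seed integer seed; recorded in all generator output.
#' @param concentrations MNase units of the titration series.
#' @param n_replicates biological replicates per condition.
#' @param bin_size bin width (bp).
#' @param depth expected fragments per sample (one concentration of one
#'   replicate).
#' @param chrom_sizes named lengths; must contain `x_name` and at least two
#'   autosomes.
#' @param x_name name of the X chromosome.
#' @param n_genes genes placed genome-wide (proportional to chromosome size).
#' @param gene_length_range uniform gene-length range (bp).
#' @param n_enhancers enhancer centers genome-wide.
#' @param peaks_per_mb_x,peaks_per_mb_auto density of binding-site peaks on
#'   the X and on autosomes (the X is more densely bound).
#' @param ces_group_sizes full-scale entry-site counts per group A/B/C.
#' @param ces_scale factor applied (rounded) to `ces_group_sizes`.
#' @param repeat_fraction approximate fraction of each chromosome masked as
#'   repeat.
#' @param baseline_log_sd lognormal sd of the per-bin baseline frequency.
#' @param slope_sd sd of the smooth background true-slope field.
#' @param peak_amplitude accessibility bump (slope units) added at peaks,
#'   scaled by peak occupancy.
#' @param perturbation_decay_scale exponential decay length (bp) of both
#'   the peak accessibility bump and its clamp-RNAi attenuation.
#' @param clamp_attenuation fraction of the peak bump removed under
#'   clamp RNAi.
#' @param msl2_window half-width (bp) around entry-site centers where
#'   msl2 RNAi acts.
#' @param msl2_effect slope decrement inside the msl2 window.
#' @param gc_effect_amplitude amplitude of the smooth GC confounder added
#'   to the observable slope (0 disables it).
#' @param gc_mean,gc_sd mean and spatial sd of the per-bin GC target field.
#' @param fragment_length_mean,fragment_length_sd,fragment_length_range
#'   truncated-normal fragment-length model (bp).
#' @param noise fragment-count noise model; `"nb"` adds overdispersion,
#'   `"none"` is the deterministic expectation (for limit checks).
#' @param nb_dispersion negative-binomial dispersion when `noise = "nb"`.
#' @param mu_floor positive floor on expected bin frequency.
#' @param startseq_mean_log,startseq_sd_log lognormal baseline of nascent
#'   transcription counts per TSS.
#' @param startseq_dispersion negative-binomial dispersion of TSS counts.
#' @param startseq_perturbed_fraction fraction of TSS perturbed under
#'   clamp RNAi.
#' @param startseq_log2fc absolute log2 effect at perturbed TSS.
#' @param startseq_x_positive,startseq_auto_positive probability that a
#'   perturbed TSS is positively regulated (decreases after RNAi) on the X
#'   and on autosomes.
#' @param qpcr_input_fraction input fraction of the qPCR percent-input
#'   model (default 1%).
#' @param qpcr_ct_input baseline input Ct (cycles).
#' @param qpcr_ct_noise_sd Gaussian Ct noise (cycles).
#' @param qpcr_efficiency per-cycle amplification factor.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       concentrations = c(1.5, 6.25, 25, 100),
                       n_replicates = 2L,
                       bin_size = 100L,
                       depth = 5e5,
                       chrom_sizes = c(chrX = 1e6, chr2L = 1e6, chr2R = 1e6),
                       x_name = "chrX",
                       n_genes = 300L,
                       gene_length_range = c(2000, 6000),
                       n_enhancers = 150L,
                       peaks_per_mb_x = 60,
                       peaks_per_mb_auto = 30,
                       ces_group_sizes = c(A = 176L, B = 43L, C = 45L),
                       ces_scale = 0.25,
                       repeat_fraction = 0.03,
                       baseline_log_sd = 0.25,
                       slope_sd = 0.12,
                       peak_amplitude = 0.3,
                       perturbation_decay_scale = 2000,
                       clamp_attenuation = 0.7,
                       msl2_window = 200,
                       msl2_effect = 0.15,
                       gc_effect_amplitude = 0.5,
                       gc_mean = 0.45, gc_sd = 0.1,
                       fragment_length_mean = 150,
                       fragment_length_sd = 15,
                       fragment_length_range = c(100, 250),
                       noise = c("poisson", "nb", "none"),
                       nb_dispersion = 0.05,
                       mu_floor = 0.02,
                       startseq_mean_log = 4, startseq_sd_log = 1,
                       startseq_dispersion = 0.05,
                       startseq_perturbed_fraction = 0.10,
                       startseq_log2fc = 1.5,
                       startseq_x_positive = 0.62,
                       startseq_auto_positive = 0.35,
                       qpcr_input_fraction = 0.01,
                       qpcr_ct_input = 22,
                       qpcr_ct_noise_sd = 0.15,
                       qpcr_efficiency = 2) {
  noise <- match.arg(noise)
  if (any(concentrations <= 0) || anyDuplicated(concentrations)) {
    stop("concentrations must be strictly positive and distinct")
  }
  if (depth <= 0) stop("depth must be positive")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  sizes <- as_chrom_sizes(chrom_sizes)
  if (!x_name %in% names(sizes)) {
    stop("chrom_sizes must contain the X chromosome '", x_name, "'")
  }
  if (length(sizes) < 3) stop("at least one X and two autosomes required")
  if (qpcr_efficiency <= 0) stop("qPCR efficiency must be positive")
  if (qpcr_input_fraction <= 0 || qpcr_input_fraction > 1) {
    stop("qpcr_input_fraction must lie in (0, 1]")
  }
  cfg <- as.list(environment())
  cfg$chrom_sizes <- sizes
  structure(cfg, class = "sim_config")
}

# Smooth standardized random field: white noise convolved with a running
# mean, then rescaled to unit sd and truncated at +/- 2.5.
smooth_field <- function(n, window = 21) {
  z <- running_mean(stats::rnorm(n + 2 * window), window)
  z <- z[(window + 1):(window + n)]
  z <- (z - mean(z)) / stats::sd(z)
  pmin(pmax(z, -2.5), 2.5)
}

# Distance (bp) from each of `pos` to the nearest of sorted `sites`.
nearest_distance <- function(pos, sites) {
  if (length(sites) == 0) return(rep(Inf, length(pos)))
  sites <- sort(sites)
  i <- findInterval(pos, sites)
  d_lo <- ifelse(i >= 1, pos - sites[pmax(i, 1)], Inf)
  d_hi <- ifelse(i < length(sites), sites[pmin(i + 1, length(sites))] - pos,
                 Inf)
  pmin(abs(d_lo), abs(d_hi))
}

rnorm_trunc <- function(n, mean, sd, range) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < range[1] | x > range[2])
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < range[1] | x[bad] > range[2]]
  }
  x
}

#' Generate a synthetic genome with known accessibility truth
#'
#' Builds chromosome sequences with a smoothly varying GC landscape,
#' non-overlapping genes, enhancer centers, occupancy-scored binding peaks,
#' X-linked entry sites in groups A/B/C, a repeat mask, and a per-bin true
#' accessibility slope for each RNAi condition:
#' * control: a smooth background field plus an exponential accessibility
#'   bump around every peak (decay `perturbation_decay_scale`, height
#'   proportional to occupancy);
#' * clamp_rnai: the peak bump attenuated by `clamp_attenuation`, so the
#'   perturbation decays with distance from peak anchors;
#' * msl2_rnai: control minus `msl2_effect` within `msl2_window` bp of
#'   entry-site centers only.
#'
#' Deterministic for a fixed `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a `synthetic_genome` list: `chrom_sizes`, `sequence`
#'   (DNAStringSet), `bins` (with GC), `genes`, `enhancer_centers`, `peaks`,
#'   `ces`, `repeat_mask`, `truth` (per-bin true slope per condition and the
#'   baseline `beta`), `config`.
#' @export
make_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  sizes <- config$chrom_sizes
  set.seed(config$seed)

  # -- feasibility: genes are placed without overlap with >= 200 bp gaps
  n_genes_chrom <- round(config$n_genes * sizes / sum(sizes))
  need <- n_genes_chrom * (max(config$gene_length_range) + 200)
  if (any(need > sizes)) {
    bad <- names(sizes)[need > sizes][1]
    stop(sprintf(
      "cannot place %d genes of up to %d bp on %s (%d bp): sizing error",
      n_genes_chrom[[bad]], max(config$gene_length_range), bad,
      as.integer(sizes[[bad]])))
  }

  # -- sequences with a smooth GC target per bin
  seqs <- Biostrings::DNAStringSet(vapply(names(sizes), function(ch) {
    L <- as.integer(sizes[[ch]])
    nb <- ceiling(L / config$bin_size)
    gc_t <- pmin(pmax(config$gc_mean + config$gc_sd * smooth_field(nb),
                      0.25), 0.7)
    p <- rep(gc_t, each = config$bin_size)[seq_len(L)]
    is_gc <- stats::runif(L) < p
    pick <- stats::runif(L) < 0.5
    base <- ifelse(is_gc, ifelse(pick, "G", "C"), ifelse(pick, "A", "T"))
    paste(base, collapse = "")
  }, character(1)))
  names(seqs) <- names(sizes)

  bins <- bin_genome(sizes, config$bin_size, fasta = seqs)

  # -- genes: sequential placement with random gaps, random strand
  genes <- do.call(rbind, lapply(names(sizes), function(ch) {
    n <- n_genes_chrom[[ch]]
    if (n == 0) return(NULL)
    len <- round(stats::runif(n, config$gene_length_range[1],
                              config$gene_length_range[2]))
    free <- as.integer(sizes[[ch]]) - sum(len)
    cuts <- sort(stats::runif(n + 1))
    gaps <- pmax(floor(free * diff(c(0, cuts)) / cuts[n + 1]), 1)
    starts <- cumsum(gaps[seq_len(n)] + c(0, len[-n]))
    data.frame(chrom = ch, start = starts, end = starts + len,
               strand = sample(c("+", "-"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  genes$id <- sprintf("g%04d", seq_len(nrow(genes)))

  # -- enhancers, peaks, entry sites, repeats
  n_enh_chrom <- round(config$n_enhancers * sizes / sum(sizes))
  enhancers <- do.call(rbind, lapply(names(sizes), function(ch) {
    data.frame(chrom = ch,
               pos = sort(round(stats::runif(n_enh_chrom[[ch]], 500,
                                             sizes[[ch]] - 500))),
               stringsAsFactors = FALSE)
  }))

  peaks <- do.call(rbind, lapply(names(sizes), function(ch) {
    rate <- if (ch == config$x_name) config$peaks_per_mb_x else
      config$peaks_per_mb_auto
    n <- max(1L, round(rate * sizes[[ch]] / 1e6))
    data.frame(chrom = ch,
               pos = sort(round(stats::runif(n, 0, sizes[[ch]] - 1))),
               occupancy = stats::rlnorm(n, 0, 0.5),
               stringsAsFactors = FALSE)
  }))

  n_ces <- round(config$ces_group_sizes * config$ces_scale)
  x_len <- as.integer(sizes[[config$x_name]])
  ces <- data.frame(
    chrom = config$x_name,
    pos = sort(round(stats::runif(sum(n_ces), 1000, x_len - 1000))),
    stringsAsFactors = FALSE)
  ces$group <- sample(rep(names(n_ces), n_ces))

  repeat_mask <- do.call(rbind, lapply(names(sizes), function(ch) {
    n <- max(1L, round(sizes[[ch]] * config$repeat_fraction / 3000))
    w <- round(stats::runif(n, 2000, 4000))
    s <- round(stats::runif(n, 0, sizes[[ch]] - w))
    data.frame(chrom = ch, start = s, end = s + w, stringsAsFactors = FALSE)
  }))

  # -- per-bin truth
  mids <- bin_midpoints(bins)
  beta <- pmin(pmax(stats::rlnorm(nrow(bins), 0, config$baseline_log_sd),
                    0.5), 2)
  control <- numeric(nrow(bins))
  bump <- numeric(nrow(bins))
  for (ch in names(sizes)) {
    idx <- which(bins$chrom == ch)
    control[idx] <- config$slope_sd * smooth_field(length(idx), 11)
    pk <- peaks[peaks$chrom == ch, ]
    occ_scaled <- pk$occupancy / mean(peaks$occupancy)
    for (j in seq_len(nrow(pk))) {
      d <- abs(mids[idx] - pk$pos[j])
      within <- d <= 8 * config$perturbation_decay_scale
      bump[idx[within]] <- bump[idx[within]] +
        config$peak_amplitude * occ_scaled[j] *
          exp(-d[within] / config$perturbation_decay_scale)
    }
  }
  clamp <- control + (1 - config$clamp_attenuation) * bump
  control <- control + bump
  msl2 <- control
  xi <- which(bins$chrom == config$x_name)
  d_ces <- nearest_distance(mids[xi], ces$pos)
  msl2[xi] <- msl2[xi] - config$msl2_effect * (d_ces <= config$msl2_window)

  truth <- data.frame(chrom = bins$chrom, start = bins$start,
                      end = bins$end, beta = beta, control = control,
                      clamp_rnai = clamp, msl2_rnai = msl2,
                      stringsAsFactors = FALSE)

  structure(list(chrom_sizes = sizes, sequence = seqs, bins = bins,
                 genes = genes, enhancer_centers = enhancers, peaks = peaks,
                 ces = ces, repeat_mask = repeat_mask, truth = truth,
                 x_name = config$x_name, config = config),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf(paste0("synthetic genome: %d chromosomes (%s bp), %d genes, ",
                     "%d peaks, %d entry sites\n"),
              length(x$chrom_sizes),
              format(sum(x$chrom_sizes), big.mark = ",",
                     scientific = FALSE),
              nrow(x$genes), nrow(x$peaks), nrow(x$ces)))
  cat(sprintf("  seed %d; entry-site groups: %s\n", x$config$seed,
              paste(names(table(x$ces$group)), table(x$ces$group),
                    sep = "=", collapse = " ")))
  invisible(x)
}

sim_conditions <- c("control", "clamp_rnai", "msl2_rnai")

# Derived, collision-free seed below 2^31 for a sub-stream.
derive_seed <- function(seed, stream, index) {
  as.integer((abs(seed) %% 1e6) * 2000 + stream * 211 + index) %% 2147483647L
}

# Expected per-bin normalized frequency matrix (bins x concentrations) for
# one condition; the observable slope is truth slope + GC confounder.
expected_frequency <- function(genome, condition) {
  cfg <- genome$config
  gc <- genome$bins$gc
  gcm <- mean(gc, na.rm = TRUE)
  gcd <- ifelse(is.na(gc), 0, gc - gcm)
  g <- cfg$gc_effect_amplitude * (gcd + (gcd^2 - mean(gcd^2)))
  slope <- genome$truth[[condition]] + g
  x <- -log(cfg$concentrations)
  xc <- x - mean(x)
  mu <- outer(genome$truth$beta, rep(1, length(x))) + outer(slope, xc)
  mu <- pmax(mu, cfg$mu_floor)
  colnames(mu) <- as.character(cfg$concentrations)
  mu
}

#' Simulate an MNase titration series
#'
#' Draws sequenced fragments for one sample (condition x replicate) at each
#' concentration of the series. The expected normalized frequency of bin b
#' at concentration c is linear in -log(c) with the condition's true slope
#' (plus the configured GC confounder); fragment counts are Poisson (or
#' negative binomial) around the expectation scaled to `depth`, fragment
#' lengths are truncated-normal around 150 bp, and fragments are returned
#' sorted per concentration.
#'
#' @param genome a [make_genome()] result.
#' @param condition one of `"control"`, `"clamp_rnai"`, `"msl2_rnai"`.
#' @param replicate replicate index (1-based).
#' @param config simulation config; defaults to the genome's.
#' @return list with `fragments` (named list of sorted BED-like data.frames,
#'   one per concentration), `expected` (bins x concentrations expected
#'   count matrix), and metadata including the derived seed.
#' @export
simulate_titration <- function(genome, condition = sim_conditions,
                               replicate = 1L, config = genome$config) {
  stopifnot(inherits(genome, "synthetic_genome"))
  if (!condition[1] %in% sim_conditions) {
    stop("unknown condition label: ", condition[1])
  }
  condition <- condition[1]
  cond_i <- match(condition, sim_conditions)
  seed_used <- derive_seed(config$seed, cond_i, replicate)
  set.seed(seed_used)

  mu <- expected_frequency(genome, condition)
  expected <- sweep(mu, 2, config$depth / colSums(mu), `*`)
  bins <- genome$bins
  sizes <- genome$chrom_sizes
  chrom_i <- match(bins$chrom, names(sizes))

  frags <- lapply(seq_along(config$concentrations), function(ci) {
    counts <- switch(config$noise,
      poisson = stats::rpois(nrow(bins), expected[, ci]),
      nb = stats::rnbinom(nrow(bins), mu = expected[, ci],
                          size = 1 / config$nb_dispersion),
      none = round(expected[, ci]))
    idx <- rep.int(seq_len(nrow(bins)), counts)
    n <- length(idx)
    mid <- bins$start[idx] +
      floor(stats::runif(n) * (bins$end[idx] - bins$start[idx]))
    len <- round(rnorm_trunc(n, config$fragment_length_mean,
                             config$fragment_length_sd,
                             config$fragment_length_range))
    start <- mid - len %/% 2L
    end <- start + len
    lim <- sizes[chrom_i[idx]]
    shift <- pmax(0L, -start) - pmax(0L, end - lim)
    start <- as.integer(start + shift)
    end <- as.integer(end + shift)
    o <- order(chrom_i[idx], start, method = "radix")
    data.frame(chrom = bins$chrom[idx][o], start = start[o], end = end[o],
               stringsAsFactors = FALSE)
  })
  names(frags) <- as.character(config$concentrations)

  list(fragments = frags, expected = expected, condition = condition,
       replicate = replicate, concentrations = config$concentrations,
       seed_used = seed_used)
}

# Perturbation labels shared by all Start-seq samples of one genome.
startseq_truth <- function(genome, config = genome$config) {
  set.seed(derive_seed(config$seed, 7L, 1L))
  g <- genome$genes
  n <- nrow(g)
  baseline <- stats::rlnorm(n, config$startseq_mean_log,
                            config$startseq_sd_log)
  perturbed <- stats::runif(n) < config$startseq_perturbed_fraction
  p_pos <- ifelse(g$chrom == genome$x_name, config$startseq_x_positive,
                  config$startseq_auto_positive)
  direction <- ifelse(!perturbed, "unchanged",
                      ifelse(stats::runif(n) < p_pos,
                             "positive_regulation", "negative_regulation"))
  data.frame(gene_id = g$id, chrom = g$chrom,
             tss = ifelse(g$strand == "+", g$start, g$end - 1L),
             strand = g$strand, baseline = baseline,
             perturbed = perturbed, direction = direction,
             stringsAsFactors = FALSE)
}

#' Simulate nascent-transcription (Start-seq) counts per TSS
#'
#' Negative-binomial counts per gene TSS. A configured fraction of TSS is
#' perturbed under `clamp_rnai`, with an X-biased probability of positive
#' regulation (abundance decreases after RNAi); perturbation labels are
#' fixed per genome so replicates and conditions share them, and are
#' attached as the `truth` attribute.
#'
#' @param genome a [make_genome()] result.
#' @param condition `"control"` or `"clamp_rnai"`.
#' @param replicate replicate index.
#' @param config simulation config; defaults to the genome's.
#' @return data.frame (gene_id, chrom, tss, strand, count) with attribute
#'   `truth`.
#' @export
simulate_startseq <- function(genome, condition = c("control", "clamp_rnai"),
                              replicate = 1L, config = genome$config) {
  condition <- match.arg(condition)
  truth <- startseq_truth(genome, config)
  mult <- rep(1, nrow(truth))
  if (condition == "clamp_rnai") {
    mult[truth$direction == "positive_regulation"] <-
      2^(-config$startseq_log2fc)
    mult[truth$direction == "negative_regulation"] <-
      2^(config$startseq_log2fc)
  }
  set.seed(derive_seed(config$seed, 8L + match(condition,
                                               c("control", "clamp_rnai")),
                       replicate))
  mu <- truth$baseline * mult
  counts <- if (config$startseq_dispersion > 0) {
    stats::rnbinom(nrow(truth), mu = mu,
                   size = 1 / config$startseq_dispersion)
  } else {
    stats::rpois(nrow(truth), mu)
  }
  out <- data.frame(gene_id = truth$gene_id, chrom = truth$chrom,
                    tss = truth$tss, strand = truth$strand, count = counts,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- truth
  attr(out, "condition") <- condition
  attr(out, "replicate") <- replicate
  out
}

#' Simulate a ChIP-qPCR Ct table
#'
#' Inverts the percent-input enrichment model of [qpcr_enrichment()]: for
#' each locus/condition/replicate, input and IP Ct values are generated so
#' that the noise-free round trip recovers the requested log2 fold
#' enrichment exactly. The internal-control locus is simulated at zero
#' enrichment.
#'
#' @param true_enrichments data.frame with columns `locus`, `condition`,
#'   `log2fe`.
#' @param n_replicates replicates per condition.
#' @param config a [sim_config()] supplying the input fraction, baseline
#'   input Ct, Ct noise sd and amplification efficiency.
#' @param control_locus name of the internal-control locus.
#' @return long-format data.frame of qPCR records (locus, role, template,
#'   condition, replicate, ct, input_fraction).
#' @export
simulate_qpcr <- function(true_enrichments, n_replicates = 3L,
                          config = sim_config(),
                          control_locus = "cg15570") {
  stopifnot(all(c("locus", "condition", "log2fe") %in%
                  names(true_enrichments)))
  if (config$qpcr_efficiency <= 0) stop("qPCR efficiency must be positive")
  set.seed(derive_seed(config$seed, 12L, 1L))
  f <- config$qpcr_input_fraction
  rows <- list()
  conds <- unique(true_enrichments$condition)
  for (cond in conds) {
    te <- true_enrichments[true_enrichments$condition == cond, ]
    loci <- c(stats::setNames(te$log2fe, te$locus),
              stats::setNames(0, control_locus))
    for (rep_i in seq_len(n_replicates)) {
      for (L in names(loci)) {
        pin <- 2^loci[[L]]   # percent input; control locus at 1
        ct_in <- config$qpcr_ct_input +
          stats::rnorm(1, 0, config$qpcr_ct_noise_sd)
        ct_ip <- ct_in - log2(1 / f) - log2(pin / 100) +
          stats::rnorm(1, 0, config$qpcr_ct_noise_sd)
        role <- if (L == control_locus) "internal_control" else "target"
        rows[[length(rows) + 1L]] <- data.frame(
          locus = L, role = role,
          template = c("IP", "input"), condition = cond,
          replicate = rep_i, ct = c(ct_ip, ct_in), input_fraction = f,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Write synthetic genome files
#'
#' Serializes a synthetic genome to standard plain-text formats: FASTA,
#' chrom.sizes TSV, genes as BED12, anchors as BED with extra columns
#' (peak occupancy; entry-site group), repeat mask BED and the truth table
#' TSV.
#'
#' @param genome a `synthetic_genome`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(genome$sequence,
                              file.path(dir, "genome.fa"))
  utils::write.table(
    data.frame(names(genome$chrom_sizes),
               as.integer(genome$chrom_sizes)),
    file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  g <- genome$genes
  bed12 <- data.frame(g$chrom, g$start, g$end, g$id, 0L, g$strand,
                      g$start, g$end, "0,0,0", 1L, g$end - g$start, 0L)
  utils::write.table(bed12, file.path(dir, "genes.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  pk <- genome$peaks
  utils::write.table(
    data.frame(pk$chrom, pk$pos, pk$pos + 1L, "peak", pk$occupancy),
    file.path(dir, "peaks.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  ce <- genome$ces
  utils::write.table(
    data.frame(ce$chrom, ce$pos, ce$pos + 1L, ce$group),
    file.path(dir, "ces.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  en <- genome$enhancer_centers
  utils::write.table(
    data.frame(en$chrom, en$pos, en$pos + 1L),
    file.path(dir, "enhancers.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(genome$repeat_mask, file.path(dir, "repeats.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(genome$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(sprintf("seed\t%d", genome$config$seed),
             file.path(dir, "metadata.tsv"))
  invisible(dir)
}
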