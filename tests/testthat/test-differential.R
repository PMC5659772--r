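# Differential accessibility: delta, moderated significance, feature
# classification, distribution summaries and randomized controls.

test_that("delta is bin-aligned, antisymmetric and shift-covariant", {
  a <- toy_track(c(1, 2, 3, 4))
  b <- toy_track(c(4, 3, 2, 1))
  expect_equal(delta_macc(a, a)$delta, rep(0, 4))
  expect_equal(delta_macc(a, b)$delta, -delta_macc(b, a)$delta)
  shifted <- b
  shifted$score <- b$score + 1
  expect_equal(delta_macc(a, shifted)$delta, delta_macc(a, b)$delta - 1)
  short <- toy_track(c(1, 2, 3))
  expect_error(delta_macc(a, short), "grids")
})

test_that("moderated t matches limma on a shared dataset", {
  skip_if_not_installed("limma")
  set.seed(42)
  n <- 500
  m <- matrix(rnorm(4 * n, sd = rep(sqrt(rchisq(n, 4) / 4), 4)), ncol = 4)
  m[1:50, 3:4] <- m[1:50, 3:4] + 2
  res <- maccr:::moderated_t(m[, 1:2], m[, 3:4])

  design <- cbind(1, c(0, 0, 1, 1))
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 1e-4)
  expect_equal(attr(res, "s02"), fit$s2.prior, tolerance = 1e-4)
  expect_equal(res$t, fit$t[, 2], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(res$p_value, fit$p.value[, 2], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("test_bins handles degenerate and invalid input", {
  a <- toy_track(rep(2, 5)); b <- toy_track(rep(2, 5))
  res <- test_bins(list(a, b), list(a, b))
  expect_equal(res$p_value, rep(1, 5))  # zero numerator, constant tracks
  expect_error(test_bins(list(a), list(a, b)), "two replicates")
})

test_that("null p-values are uniform and power is adequate (gaussian)", {
  set.seed(7)
  n <- 5000
  ctl <- matrix(rnorm(2 * n), ncol = 2)
  rna <- matrix(rnorm(2 * n), ncol = 2)
  res <- maccr:::moderated_t(ctl, rna)
  expect_gt(stats::ks.test(res$p_value, "punif")$p.value, 0.01)
  expect_lt(mean(res$p_value < 0.05), 1.5 * 0.05)
  expect_lt(mean(res$p_value < 0.01), 1.5 * 0.01)
  res2 <- maccr:::moderated_t(ctl, rna + 3)
  expect_gt(mean(res2$p_value < 0.05), 0.8)
})

test_that("region classification follows the documented windows", {
  bins <- bin_genome(c(chr1 = 10000), bin_size = 100)
  genes <- data.frame(chrom = "chr1", start = 1000, end = 3000,
                      strand = "+", id = "g1")
  enh <- data.frame(chrom = "chr1", pos = 5050)
  cat <- classify_regions(bins, genes, enh)
  at <- function(start) as.character(cat[bins$start == start])
  expect_equal(at(600), "tss_tts")     # upstream window [500,1000)
  expect_equal(at(1500), "gene_body")
  expect_equal(at(3200), "tss_tts")    # downstream window [3000,3500)
  expect_equal(at(5000), "enhancer")   # center 5050 +/- 500
  expect_equal(at(8000), "unannotated")
  expect_error(classify_regions(bins,
                                data.frame(chrom = "chr1", start = 10,
                                           end = 5, strand = "+",
                                           id = "bad")),
               "end < start")
})

test_that("classification agrees with a brute-force per-bp scan", {
  set.seed(21)
  for (rep_i in 1:10) {
    L <- 20000
    bins <- bin_genome(c(c1 = L), bin_size = 100)
    ng <- sample(2:5, 1)
    starts <- sort(sample(seq(600, L - 2500, by = 10), ng))
    genes <- data.frame(chrom = "c1", start = starts,
                        end = starts + sample(500:1800, ng, replace = TRUE),
                        strand = sample(c("+", "-"), ng, replace = TRUE),
                        id = paste0("g", seq_len(ng)))
    enh <- data.frame(chrom = "c1",
                      pos = sample(600:(L - 600), sample(1:3, 1)))
    got <- as.character(classify_regions(bins, genes, enh))

    mids <- (bins$start + bins$end) %/% 2
    want <- vapply(mids, function(p) {
      in_tss <- any((p >= genes$start - 500 & p < genes$start) |
                      (p >= genes$end & p < genes$end + 500))
      in_enh <- any(p >= enh$pos - 500 & p < enh$pos + 500)
      in_body <- any(p >= genes$start & p < genes$end)
      if (in_tss) "tss_tts" else if (in_enh) "enhancer" else
        if (in_body) "gene_body" else "unannotated"
    }, character(1))
    expect_identical(got, want)
  }
})

test_that("category counts sum to significant bins and normalize by bp", {
  diff <- data.frame(p_value = c(rep(0.001, 10), rep(0.5, 6)))
  category <- factor(c(rep("gene_body", 10), rep("unannotated", 6)),
                     levels = c("gene_body", "tss_tts", "enhancer",
                                "unannotated"))
  tab <- category_counts(diff, category)
  expect_equal(tab$n_significant, c(10, 0, 0, 0))
  expect_equal(sum(tab$n_significant), sum(diff$p_value < 0.01))
  expect_equal(category_counts(diff, category,
                               p_threshold = 0)$n_significant,
               rep(0L, 4))

  # normalized counts divide by genome-fraction: 10% with 5 hits beats
  # 50% with 5 hits ten-fold vs two-fold
  genes <- data.frame(chrom = "c1", start = 500, end = 1500, strand = "+",
                      id = "g1")
  bins <- bin_genome(c(c1 = 10000), 100)
  cat2 <- classify_regions(bins, genes)
  d2 <- data.frame(p_value = ifelse(cat2 %in% c("gene_body", "tss_tts"),
                                    0.001, 1))
  tab2 <- category_counts(d2, cat2, normalize = TRUE, genes = genes,
                          chrom_sizes = c(c1 = 10000))
  fr <- tab2$genome_fraction
  expect_equal(fr[tab2$category == "gene_body"], 0.10)   # [500,1500)
  expect_equal(fr[tab2$category == "tss_tts"], 0.10)     # 2 x 500 bp
  expect_equal(tab2$normalized,
               ifelse(fr > 0, tab2$n_significant / fr, NA_real_))
  expect_true(is.na(tab2$normalized[tab2$category == "enhancer"]))
})

test_that("chromosome summaries use the stated notch convention", {
  bins <- bin_genome(c(chrX = 5000, chr2L = 5000), 100)
  set.seed(3)
  base <- rnorm(50)
  tr <- macc_track(bins, c(base + 0.5, base))
  out <- chromosome_distribution(list(control = tr), "chrX")
  s <- out$summary
  xmed <- s$median[s$group == "X"]
  amed <- s$median[s$group == "autosomes"]
  expect_equal(xmed - amed, 0.5, tolerance = 1e-9)

  # notch of 1..100 with type-7 quartiles
  tr2 <- macc_track(bin_genome(c(chrX = 10000, chr2L = 100), 100),
                    c(1:100, 0))
  s2 <- chromosome_distribution(list(c = tr2), "chrX")$summary
  iqr <- unname(diff(quantile(1:100, c(0.25, 0.75), type = 7)))
  expect_equal(s2$notch[s2$group == "X"], 1.58 * iqr / sqrt(100))
  expect_equal(s2$notch[s2$group == "X"], 1.58 * 49.5 / 10)

  # well-separated samples are highly significant; identical ones are not
  set.seed(8)
  big <- macc_track(bin_genome(c(chrX = 1e5, chr2L = 1e5), 100),
                    c(rnorm(1000) + 0.5, rnorm(1000)))
  outb <- chromosome_distribution(list(c = big), "chrX")
  expect_lt(outb$tests$p[outb$tests$comparison == "X_vs_autosomes"], 1e-6)
  same <- chromosome_distribution(list(a = big, b = big), "chrX")
  psame <- same$tests$p[same$tests$comparison == "a_vs_b"]
  expect_true(all(psame > 0.95))
})

test_that("direction fractions partition genes with nonzero change", {
  expect_equal(direction_fractions(c(-1, -1, -1, 1)),
               list(percent_decrease = 75, percent_increase = 25,
                    n_zero = 0L, n = 4L))
  expect_equal(direction_fractions(c(-2, -3))$percent_decrease, 100)
  x <- c(-1, 2, 0, 3, -4, 0)
  df <- direction_fractions(x)
  expect_equal(df$percent_decrease + df$percent_increase, 100)
  expect_equal(df$n_zero, 2L)
  expect_error(direction_fractions(numeric(0)), "empty")
})

test_that("gene-level deltas average gene-body bins", {
  bins <- bin_genome(c(c1 = 1000), 100)
  d <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                  delta = 1:10)
  genes <- data.frame(chrom = "c1", start = c(0, 500), end = c(300, 900),
                      strand = "+", id = c("a", "b"))
  gd <- gene_deltas(d, genes)
  expect_equal(unname(gd["a"]), mean(1:3))
  expect_equal(unname(gd["b"]), mean(6:9))
})

test_that("randomized sites avoid the mask and are reproducible", {
  sizes <- c(c1 = 10000, c2 = 10000)
  mask <- data.frame(chrom = "c1", start = 0, end = 9000)
  s1 <- randomized_sites(200, sizes, mask, seed = 5)
  s2 <- randomized_sites(200, sizes, mask, seed = 5)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 200)
  on_c1 <- s1$chrom == "c1"
  expect_true(all(s1$pos[on_c1] >= 9000))
  full <- data.frame(chrom = c("c1", "c2"), start = 0, end = 10000)
  expect_error(randomized_sites(10, sizes, full), "covers")
})
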