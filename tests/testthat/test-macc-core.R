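# Binning, counting, normalization and the accessibility statistic.

test_that("bin_genome tiles chromosomes with a short final bin", {
  b <- bin_genome(c(chr1 = 250), bin_size = 100)
  expect_equal(b$start, c(0, 100, 200))
  expect_equal(b$end, c(100, 200, 250))
  expect_true(all(is.na(b$gc)))

  # two chromosomes stay in the given order, tiling each fully
  b2 <- bin_genome(c(chrX = 130, chrA = 210), bin_size = 100)
  expect_equal(b2$chrom, c("chrX", "chrX", "chrA", "chrA", "chrA"))
  expect_equal(sum(b2$end - b2$start), 340)
})

test_that("per-bin GC is computed over non-N bases", {
  seqs <- Biostrings::DNAStringSet(c(
    chr1 = paste0(strrep("GGCC", 25),     # bin 1: all GC
                  strrep("AT", 50),       # bin 2: no GC
                  paste0(strrep("N", 92), "GCGCATAT"),  # bin 3: 50% over 8
                  strrep("N", 52))))      # bin 4 (short): all N
  b <- bin_genome(c(chr1 = 352), bin_size = 100, fasta = seqs)
  expect_equal(b$gc, c(1, 0, 0.5, NA))
})

test_that("bin_genome rejects FASTA/chrom.sizes mismatches", {
  seqs <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGT"))
  expect_error(bin_genome(c(chr2 = 8), fasta = seqs), "chr2")
  expect_error(bin_genome(c(chr1 = 9), fasta = seqs), "mismatch")
})

test_that("hotspot filter masks only extreme positions", {
  # uniform coverage: zero spread, so nothing masked (with a warning)
  fr <- data.frame(chrom = "c", start = 0:99, end = 150:249)
  expect_warning(m <- filter_hotspots(fr), "zero spread")
  expect_equal(nrow(m$positions), 0)

  # one position with count 1000 among singletons is masked at Z >= 7
  fr2 <- rbind(fr, data.frame(chrom = "c", start = rep(50L, 1000),
                              end = rep(200L, 1000)))
  m2 <- filter_hotspots(fr2)
  expect_equal(m2$positions$pos, 50)
  z50 <- (1001 - mean(c(rep(1, 99), 1001))) / sd(c(rep(1, 99), 1001))
  expect_gte(z50, 7)

  # infinite threshold masks nothing
  expect_equal(nrow(filter_hotspots(fr2, z_threshold = Inf)$positions), 0)

  # a single covered position cannot define a Z score
  expect_warning(filter_hotspots(fr[rep(1, 5), ]), "zero spread")
})

test_that("fragments are assigned to bins by midpoint with size filtering", {
  bins <- bin_genome(c(chr1 = 1000), bin_size = 100)
  fr <- data.frame(chrom = "chr1", start = 150, end = 250)
  counts <- count_fragments(fr, bins)
  expect_equal(which(counts == 1), 3)  # midpoint 200 -> bin [200,300)

  # fragment of length 90 dropped by the default [100,200] window
  fr2 <- data.frame(chrom = "chr1", start = c(150, 100), end = c(250, 190))
  c2 <- count_fragments(fr2, bins)
  expect_equal(sum(c2), 1)
  expect_equal(attr(c2, "n_dropped_size"), 1)

  # conservation: 10 identical fragments land in one bin
  fr3 <- fr[rep(1, 10), ]
  c3 <- count_fragments(fr3, bins)
  expect_equal(as.integer(c3), c(0, 0, 10, rep(0, 7)))
  expect_equal(sum(c3), attr(c3, "n_kept"))

  # beyond-chromosome fragment errors naming the record
  expect_error(
    count_fragments(data.frame(chrom = "chr1", start = 950, end = 1100),
                    bins),
    "fragment 1")
  # masked start positions are excluded
  mask <- filter_hotspots(rbind(fr3, data.frame(chrom = "chr1",
                                                start = 0:49,
                                                end = 150:199)))
  expect_equal(mask$positions$pos, 150)
  c4 <- count_fragments(fr3, bins, mask = mask)
  expect_equal(sum(c4), 0)
  expect_equal(attr(c4, "n_dropped_mask"), 10)
})

test_that("library normalization is counts-per-million and refuses reuse", {
  bins <- bin_genome(c(chr1 = 300), bin_size = 100)
  counts <- matrix(c(4, 1e6 - 4, 0, 10, 2e6 - 10, 0), ncol = 2)
  tc <- titration_counts(bins, c(1.5, 100), counts)
  tn <- normalize_library(tc)
  expect_equal(unname(tn$counts[1, 2]), 5)  # 10 of 2e6 -> 5 per million
  expect_equal(unname(colSums(tn$counts)), c(1e6, 1e6))
  expect_error(normalize_library(tn), "already normalized")
  tc0 <- titration_counts(bins, c(1.5, 100), matrix(0, 3, 2))
  expect_error(normalize_library(tc0), "zero-total")
})

test_that("slope matches a long-hand least-squares oracle on random bins", {
  set.seed(101)
  conc <- c(1.5, 6.25, 25, 100)
  x <- -log(conc)
  n <- 1000
  y <- matrix(rexp(n * 4, rate = 1 / 50), ncol = 4)
  bins <- bin_genome(c(chr1 = n * 100), bin_size = 100)
  tc <- titration_counts(bins, conc, y, normalized = TRUE)
  track <- compute_macc(tc)
  oracle <- vapply(seq_len(n), function(i) ols_slope(x, y[i, ]),
                   numeric(1))
  expect_lt(max(abs(track$score - oracle)), 1e-9)
})

test_that("slope sign convention and degenerate cases", {
  conc <- c(100, 25, 6.25, 1.5)
  bins <- bin_genome(c(chr1 = 300), bin_size = 100)
  mk <- function(v) {
    compute_macc(titration_counts(bins, conc,
                                  matrix(rep(v, each = 3), nrow = 3),
                                  normalized = TRUE))$score[1]
  }
  # rising frequency toward low concentration: open chromatin, positive
  expect_equal(mk(c(2, 4, 8, 10)),
               ols_slope(-log(conc), c(2, 4, 8, 10)), tolerance = 1e-12)
  expect_equal(round(mk(c(2, 4, 8, 10)), 2), 2.00)
  expect_equal(mk(c(10, 8, 4, 2)), -mk(c(2, 4, 8, 10)), tolerance = 1e-12)
  expect_identical(mk(c(3, 3, 3, 3)), 0)

  tc1 <- titration_counts(bins, 25, matrix(1, 3, 1), normalized = TRUE)
  expect_error(compute_macc(tc1), "two distinct concentrations")
})

test_that("GC correction removes an injected trend and little else", {
  set.seed(11)
  n <- 2000
  gc <- runif(n, 0.3, 0.7)
  base <- rnorm(n)
  bins <- bin_genome(c(chr1 = n * 100), bin_size = 100)
  bins$gc <- gc

  # scores independent of gc: correction is (nearly) a no-op
  t0 <- gc_correct(macc_track(bins, base))
  expect_lt(max(abs(t0$score - base)), 0.15)
  expect_lt(abs(cor(t0$score, gc)), 0.05)

  # additive trend in the score is removed
  t1 <- gc_correct(macc_track(bins, base + 3 * (gc - 0.5)^2 + 2 * gc))
  expect_lt(abs(cor(t1$score, gc)), 0.05)
  expect_gt(cor(t1$score, base), 0.95)

  # idempotence up to smoother tolerance
  t2 <- gc_correct(t1)
  expect_lt(max(abs(t2$score - t1$score)), 0.05)

  # refuses with too few annotated bins
  small <- macc_track(bin_genome(c(chr1 = 1000), 100), rnorm(10))
  expect_warning(out <- gc_correct(small), "fewer than 100")
  expect_false(out$gc_corrected)
})

test_that("median shift centers samples and preserves differences", {
  tr <- toy_track(c(5, 1, 2, 9, 4))
  sh <- median_shift(tr)
  expect_equal(median(sh$score), 0)
  expect_equal(median_shift(toy_track(rep(3, 5)))$score, rep(0, 5))
  tr2 <- toy_track(c(0, 2, 1, 7, 3))
  d0 <- tr$score - tr2$score
  d1 <- median_shift(tr)$score - median_shift(tr2)$score
  expect_equal(d1 - d1[1], d0 - d0[1])
})

test_that("doubling X reads renormalizes and keeps slopes invariant", {
  bins <- bin_genome(c(chrX = 200, chr2L = 200), bin_size = 100)
  counts <- matrix(c(5, 10, 20, 40,
                     10, 20, 40, 80), ncol = 2)
  tc <- titration_counts(bins, c(1.5, 100), counts)
  dbl <- double_x_reads(tc, "chrX")
  expect_true(dbl$normalized)
  # X bins (5,10 and 10,20) doubled pre-normalization
  expect_equal(unname(dbl$library_sizes), c(90, 180))
  expect_error(double_x_reads(tc, "chr9"), "unknown chromosome")
  expect_error(double_x_reads(dbl, "chrX"), "raw counts")

  # when every column scales uniformly, CPM (and hence slopes) of an
  # all-autosome dataset are unchanged
  binsA <- bin_genome(c(chr2L = 300), bin_size = 100)
  y <- matrix(c(1, 2, 3, 2, 4, 6, 4, 8, 12, 8, 16, 24), ncol = 4)
  tA <- titration_counts(binsA, c(1.5, 6.25, 25, 100), y)
  s1 <- compute_macc(normalize_library(tA))$score
  tA2 <- titration_counts(binsA, c(1.5, 6.25, 25, 100), y * 5)
  expect_equal(compute_macc(normalize_library(tA2))$score, s1)
})
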