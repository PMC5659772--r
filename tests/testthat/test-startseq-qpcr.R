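# Nascent-transcription differential, regulation summaries and qPCR math.

test_that("observed TSS is the signal argmax with lower-coordinate ties", {
  genes <- data.frame(chrom = "c1", start = 1000, end = 3000, strand = "+",
                      id = "g1")
  spike <- function(pos, n) data.frame(chrom = "c1", pos = rep(pos, n),
                                       strand = "+")
  # spike at the annotated start
  expect_equal(define_obstss(spike(1000, 5), genes)$obs_tss, 1000)
  # stronger spike 40 bp downstream wins
  r <- rbind(spike(1000, 3), spike(1040, 7))
  expect_equal(define_obstss(r, genes)$obs_tss, 1040)
  # tie: lower coordinate
  r2 <- rbind(spike(1040, 5), spike(990, 5))
  expect_equal(define_obstss(r2, genes)$obs_tss, 990)
  # zero-signal genes are excluded; wrong strand does not count
  r3 <- data.frame(chrom = "c1", pos = 1000, strand = "-")
  expect_equal(nrow(define_obstss(r3, genes)), 0)
  expect_error(define_obstss(data.frame(chrom = "c1", pos = 1)[0, ],
                             genes), "stranded")
})

test_that("differential start-RNA excludes empty rows and calibrates", {
  set.seed(15)
  n <- 3000
  lambda <- rlnorm(n, 4, 1)
  counts <- cbind(rpois(n, lambda), rpois(n, lambda),
                  rpois(n, lambda), rpois(n, lambda))
  counts[1:5, ] <- 0
  rownames(counts) <- paste0("t", seq_len(n))
  cond <- c("control", "control", "clamp_rnai", "clamp_rnai")
  res <- differential_start(counts, cond)
  expect_equal(attr(res, "n_excluded"), 5)
  expect_equal(nrow(res), n - 5)
  # identical generative conditions: about alpha significant
  expect_lt(abs(mean(res$p_value < 0.05) - 0.05), 0.02)
  expect_true(all(res$direction[res$p_value >= 0.05] == "unchanged"))
  expect_error(differential_start(counts[, 1:3], cond[1:3]),
               "two replicates")
})

test_that("perturbed fraction is recovered from simulated counts", {
  cfg <- sim_config(seed = 23, n_genes = 600,
                    gene_length_range = c(500, 1500))
  g <- make_genome(cfg)
  cols <- list(simulate_startseq(g, "control", 1),
               simulate_startseq(g, "control", 2),
               simulate_startseq(g, "clamp_rnai", 1),
               simulate_startseq(g, "clamp_rnai", 2))
  counts <- do.call(cbind, lapply(cols, `[[`, "count"))
  rownames(counts) <- cols[[1]]$gene_id
  res <- differential_start(counts, c("control", "control",
                                      "clamp_rnai", "clamp_rnai"))
  truth <- attr(cols[[1]], "truth")
  truth <- truth[match(res$id, truth$gene_id), ]

  # the test's own false-positive rate on this count model, from a
  # matched all-control split (the independent null oracle)
  null_cols <- lapply(3:6, function(r) simulate_startseq(g, "control", r))
  null_counts <- do.call(cbind, lapply(null_cols, `[[`, "count"))
  rownames(null_counts) <- null_cols[[1]]$gene_id
  null_res <- differential_start(null_counts, c("control", "control",
                                                "rnai", "rnai"))
  fpr <- mean(null_res$p_value < 0.05)

  # at a large effect every perturbed TSS is detected, so the recovered
  # changed fraction is ~ true fraction + fpr * (1 - fraction)
  p_true <- mean(truth$perturbed)
  expected <- p_true + fpr * (1 - p_true)
  n <- nrow(res)
  tol <- 3 * sqrt(expected * (1 - expected) / n) + 0.02
  expect_lt(abs(mean(res$p_value < 0.05) - expected), tol)
  # direction labels agree with truth for significant, truly perturbed TSS
  hit <- res$p_value < 0.05 & truth$perturbed
  expect_gt(mean(res$direction[hit] == truth$direction[hit]), 0.9)
})

test_that("regulation percentages use one-decimal rounding", {
  mk <- function(chrom, n, sig, pos = 0) {
    data.frame(chrom = chrom,
               p_value = c(rep(0.01, sig), rep(0.5, n - sig)),
               direction = c(rep("positive_regulation", pos),
                             rep("negative_regulation", sig - pos),
                             rep("unchanged", n - sig)),
               stringsAsFactors = FALSE)
  }
  # the printed male worked example: 1,007 of 9,740 -> 10.3%
  male <- mk("chrX", 9740, 1007, pos = 624)
  sm <- regulation_summary(male, alpha = 0.05)
  expect_equal(sm$pct_changed[sm$group == "all"], 10.3)
  expect_equal(sm$pct_positive[sm$group == "all"], round(62.0, 1),
               tolerance = 0.05)
  # the printed female worked example: 680 of 10,067 -> 6.8%
  female <- mk("chrX", 10067, 680)
  expect_equal(regulation_summary(female,
                                  alpha = 0.05)$pct_changed[2], 6.8)
  # zero significant: 0.0% and undefined direction split
  none <- mk("chr2L", 50, 0)
  sn <- regulation_summary(none, alpha = 0.05)
  expect_equal(sn$pct_changed, c(0, 0))
  expect_true(all(is.na(sn$pct_positive)))
  # X vs autosome grouping appears when requested
  both <- rbind(mk("chrX", 100, 12), mk("chr2L", 100, 6))
  sb <- regulation_summary(both, x_name = "chrX", alpha = 0.05)
  expect_equal(sb$pct_changed[sb$group == "X"], 12)
  expect_equal(sb$pct_changed[sb$group == "autosomes"], 6)
})

test_that("expression quartiles follow the split convention", {
  q <- expression_quartiles(1:8)
  expect_equal(as.character(q), rep(paste0("Q", 1:4), each = 2))
  expect_warning(expression_quartiles(rep(7, 4)), "degenerate")
  m <- cbind(1:8, 1:8)
  expect_equal(as.character(expression_quartiles(m)), as.character(q))
})

test_that("percent-input and enrichment identities hold", {
  # input_fraction 1% -> dilution adjustment log2(100) cycles
  expect_equal(percent_input(22 - log2(100), 22), 100)
  expect_equal(percent_input(25, 22, input_fraction = 1), 100 * 2^-3)
  expect_error(percent_input(20, 20, efficiency = 0), "positive")

  # target with Cts identical to the internal control -> log2FE 0
  rec <- data.frame(locus = rep(c("tgt", "ctl"), each = 2),
                    role = rep(c("target", "internal_control"), each = 2),
                    template = rep(c("IP", "input"), 2),
                    condition = "control", replicate = 1,
                    ct = c(24, 20, 24, 20), input_fraction = 0.01)
  est <- qpcr_enrichment(rec)
  expect_equal(est$summary$mean_log2fe, c(0, 0))

  # missing input Ct errors
  expect_error(qpcr_enrichment(rec[rec$template == "IP", ]),
               "missing or duplicated")
})

test_that("between-condition t-test detects a changed locus", {
  te <- data.frame(locus = rep("site", 2),
                   condition = c("control", "clamp_rnai"),
                   log2fe = c(3, 0.5))
  cfg <- sim_config(seed = 31, qpcr_ct_noise_sd = 0.05)
  rec <- simulate_qpcr(te, n_replicates = 3, config = cfg)
  est <- qpcr_enrichment(rec)
  expect_lt(est$tests$p[est$tests$locus == "site"], 0.01)
  ms <- est$summary[est$summary$locus == "site", ]
  expect_equal(ms$mean_log2fe[ms$condition == "control"], 3,
               tolerance = 0.2)
  expect_true(all(ms$n == 3))
})

test_that("delta-Ct relative abundance averages Ct before the power", {
  expect_equal(relative_abundance(20, 20), 1)
  expect_equal(relative_abundance(21, 20), 0.5)
  # mean-of-Ct first differs from mean-of-ratios; the former is documented
  tgt <- c(20, 22); ref <- c(20, 20)
  expect_equal(relative_abundance(tgt, ref), 2^(20 - 21))
  expect_false(isTRUE(all.equal(relative_abundance(tgt, ref),
                                mean(2^(ref - tgt)))))
  expect_error(relative_abundance(c(20, NA), c(20, 20)), "missing")
  expect_error(relative_abundance(c(20, 21), 20), "paired")
})
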