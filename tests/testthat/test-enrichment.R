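test_that("feature preparation keeps top scores and extends short peaks", {
  set.seed(FIXTURE_SEED)
  raw <- data.frame(chrom = "chr1",
                    start = seq(0L, by = 5000L, length.out = 6000L))
  raw$end <- raw$start + 1500L
  raw$score <- stats::runif(6000)
  f <- prepare_features(raw)
  expect_equal(nrow(f), 5000L)
  expect_gte(min(f$score), sort(raw$score, decreasing = TRUE)[5000])
  # 200 bp peak: extended to 1000 bp centered on its midpoint
  short <- data.frame(chrom = "chr1", start = 10000L, end = 10200L)
  e <- prepare_features(short)
  expect_equal(e$end - e$start, 1000L)
  expect_equal((e$start + e$end) / 2, (10000 + 10200) / 2)
  # 1500 bp peak unchanged
  expect_equal(prepare_features(raw[1, c("chrom", "start", "end")]),
               raw[1, c("chrom", "start", "end")])
  # scores required only when selection applies
  expect_error(prepare_features(raw[, c("chrom", "start", "end")]))
})

test_that("background sampling reproduces the observed distance distribution", {
  w <- world()
  lens <- w$sim$chrom_lengths
  bg <- sample_background(w$calls, w$sim$tss_table, 10000L, lens,
                          seed = FIXTURE_SEED)
  expect_true(all(bg$start >= 0 & bg$end <= lens[bg$chrom]))
  # sampled distances track the observed interaction distances
  # (two-sample KS < 0.05 at n = 10^4)
  pd <- w$calls[w$calls$type == "PD" & !w$calls$trans, ]
  ks <- suppressWarnings(stats::ks.test(bg$sampled_distance, pd$distance))
  expect_lt(unname(ks$statistic), 0.05)
  # the regions are actually centered that far from their anchor TSS
  # (up to clipping at chromosome bounds, rare at this scale)
  mid <- (bg$start + bg$end) / 2
  expect_gte(mean(abs(abs(mid - bg$anchor_tss) - bg$sampled_distance) <=
                    1), 0.99)
  # determinism
  bg2 <- sample_background(w$calls, w$sim$tss_table, 10000L, lens,
                           seed = FIXTURE_SEED)
  expect_identical(bg, bg2)
  # degenerate distance distribution: all regions 50 kb from some TSS
  one <- w$calls[which(w$calls$type == "PD" & !w$calls$trans)[1], ]
  one$distance <- 50000
  one$end_b <- one$start_b + 100L
  bg3 <- sample_background(one, w$sim$tss_table, 50L, lens, seed = 1L)
  mid3 <- (bg3$start + bg3$end) / 2
  expect_true(all(abs(abs(mid3 - bg3$anchor_tss) - 50000) <= 50))
  expect_error(sample_background(one[0, ], w$sim$tss_table, 5L, lens))
})

test_that("overlap signal and its chi-squared match hand computation", {
  # 40/100 observed vs 20/100 expected: signal 2, chi2 25, p ~ 5.7e-7
  regions <- data.frame(chrom = "c", start = seq(0L, by = 10000L,
                                                 length.out = 100L))
  regions$end <- regions$start + 100L
  feats <- regions[1:40, ]                       # overlap first 40
  background <- data.frame(chrom = "c",
                           start = seq(2e6, by = 10000L, length.out = 100L))
  background$end <- background$start + 100L
  feats_bg <- background[1:20, ]                 # expected 20/100
  res <- overlap_signal(regions, rbind(feats, feats_bg), background)
  expect_equal(res$observed_fraction, 0.4)
  expect_equal(res$expected_fraction, 0.2)
  expect_equal(res$signal, 2.0)
  expect_equal(res$chi2, 25.0)
  expect_equal(res$p, 5.7e-7, tolerance = 0.01)
  # observed == expected: signal 1, p = 1
  res2 <- overlap_signal(background, feats_bg, background)
  expect_equal(res2$signal, 1.0)
  expect_equal(res2$p, 1.0)
  # total depletion
  res3 <- overlap_signal(regions[41:100, ], feats_bg, background)
  expect_equal(res3$signal, 0.0)
  # expected 0: not applicable
  far <- data.frame(chrom = "c", start = 9e6, end = 9.1e6)
  expect_true(is.na(overlap_signal(far, feats, background)$signal))
})

test_that("TAD containment partitions and classifies correctly", {
  tads <- data.frame(chrom = "c", start = c(0L, 100000L),
                     end = c(100000L, 200000L))
  lens <- c(c = 300000L)
  within <- make_calls("P1", "F1", "PD", chrom_a = "c", start_a = 10000L,
                       end_a = 10100L, chrom_b = "c", start_b = 50000L,
                       end_b = 50100L, distance = 40000)
  spanning <- make_calls("P2", "F2", "PD", chrom_a = "c", start_a = 50000L,
                         end_a = 50100L, chrom_b = "c", start_b = 150000L,
                         end_b = 150100L, distance = 100000)
  outside <- make_calls("P3", "F3", "PD", chrom_a = "c", start_a = 50000L,
                        end_a = 50100L, chrom_b = "c", start_b = 250000L,
                        end_b = 250100L, distance = 200000)
  calls <- rbind(within, spanning, outside)
  class(calls) <- c("hicap_calls", "data.frame")
  rep_ <- tad_containment(calls, tads, lens, bins = c(1e6),
                          n_control = 500L, seed = FIXTURE_SEED)
  tab <- rep_$table
  expect_equal(tab$obs_within + tab$obs_spanning + tab$obs_outside, 1)
  expect_equal(tab$ctrl_within + tab$ctrl_spanning + tab$ctrl_outside, 1)
  expect_equal(tab$obs_within, 1 / 3)
  expect_equal(tab$obs_spanning, 1 / 3)
  expect_equal(tab$obs_outside, 1 / 3)
  expect_error(tad_containment(make_calls("P", "F", "PD", trans = TRUE,
                                          distance = NA),
                               tads, lens))
})

test_that("RPKM follows its definition and scaling law", {
  regions <- data.frame(chrom = "c", start = 0L, end = 1000L)
  reads <- data.frame(chrom = "c", pos = seq_len(10) * 50L)
  expect_equal(region_rpkm(regions, reads, 1e6), 10.0)
  expect_equal(region_rpkm(regions, reads[0, ], 1e6), 0.0)
  expect_equal(region_rpkm(regions, reads, 2e6),
               region_rpkm(regions, reads, 1e6) / 2)
  expect_error(region_rpkm(data.frame(chrom = "c", start = 5L, end = 5L),
                           reads, 1e6))
  # linearity: merged disjoint regions equal the combined count/length
  two <- data.frame(chrom = "c", start = c(0L, 1000L), end = c(1000L, 3000L))
  r2 <- region_rpkm(two, reads, 1e6)
  merged <- data.frame(chrom = "c", start = 0L, end = 3000L)
  counts <- r2 * (two$end - two$start)            # back to counts * 1e9/N
  expect_equal(region_rpkm(merged, reads, 1e6),
               sum(counts) / (3000))
})

test_that("eRNA analysis separates expressed planted regions from matched noise", {
  w <- world()
  res <- erna_analysis(w$calls, w$sim$gene_annotation, w$om$gro_reads,
                       w$sim$tss_table, w$sim$chrom_lengths,
                       seed = FIXTURE_SEED)
  expect_equal(res$table$threshold, c(0.1, 1.0))
  expect_true(all(res$table$frac_observed >= res$table$frac_random))
  # planted eRNA signal should be detected at desk scale
  expect_lt(res$table$p[1], 0.05)
  # genic distal regions are excluded
  expect_lt(res$intergenic_fraction, 1)
  # all-vs-none exceedance at n >= 10 is significant by hand chi-squared
  ts <- hicapr:::chisq_gof(c(10L, 0L), c(0.05, 0.95))
  expect_lt(ts$p, 0.05)
})

test_that("expression correlation sums multi-distal RPKMs and floors its p", {
  gid <- sprintf("g%02d", 1:8)
  distal <- stats::setNames(seq_len(16), paste0("F", 1:16))
  genes <- stats::setNames(seq(2, 30, by = 4), gid)
  pairing <- data.frame(distal_id = paste0("F", 1:16),
                        gene_id = rep(gid, each = 2))
  # summed distal RPKM ranks identically to gene RPKM: rho = 1, and with
  # 8 distinct ranks a permutation ties it only ~1/8! of the time
  res <- expression_correlation(distal, genes, pairing, n_perm = 1000L,
                                seed = FIXTURE_SEED)
  expect_equal(res$rho, 1.0)
  expect_equal(res$perm_p, 0.001)   # floor 1/n_perm
  # anti-ranked: rho = -1
  res2 <- expression_correlation(distal, stats::setNames(rev(genes), gid),
                                 pairing, n_perm = 100L, seed = 1L)
  expect_equal(res2$rho, -1.0)
  expect_error(expression_correlation(distal, genes * 0, pairing))
})
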