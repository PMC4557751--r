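# minimal filtered-pairs table for counting
fpairs <- function(promoter1, promoter2, frag1, frag2, replicate = "rep1") {
  n <- max(length(promoter1), length(frag1))
  data.frame(read_id = sprintf("r%d", seq_len(n)),
             chrom1 = rep("chrT", n), pos1 = rep(0L, n),
             strand1 = rep("+", n),
             chrom2 = rep("chrT", n), pos2 = rep(0L, n),
             strand2 = rep("-", n),
             frag1 = rep_len(frag1, n), frag2 = rep_len(frag2, n),
             promoter1 = rep_len(promoter1, n),
             promoter2 = rep_len(promoter2, n),
             replicate = rep_len(replicate, n),
             validity_class = rep("valid", n),
             stringsAsFactors = FALSE)
}

test_that("support counting accumulates per promoter, fragment, replicate", {
  x <- fpairs(promoter1 = rep("P1", 4), promoter2 = NA,
              frag1 = 1L, frag2 = 9L)
  cnt <- count_support(x)
  expect_equal(cnt$n, 4L)
  expect_equal(cnt$anchor, "P1")
  expect_equal(cnt$partner, "F9")
  expect_equal(cnt$type, "PD")

  # both ends on promoter targets: PP count, no PD count, canonical key
  y <- count_support(fpairs("P2", "P1", 1L, 2L))
  expect_equal(y$type, "PP")
  expect_equal(c(y$anchor, y$partner), c("P1", "P2"))
  y2 <- count_support(fpairs("P1", "P2", 2L, 1L))
  expect_equal(y2[, c("anchor", "partner", "type", "n")],
               y[, c("anchor", "partner", "type", "n")])

  # empty input
  expect_equal(nrow(count_support(fpairs(character(), character(),
                                         integer(), integer()))), 0L)
})

test_that("calling requires min_support in every replicate", {
  fm <- digest_genome(genome_with_cuts(9000, c(1000, 5000)))
  tss <- data.frame(chrom = "chrT", tss = 2000, promoter_id = "P1",
                    gene_id = "G1")
  pr <- design_probe_targets(tss, fm)
  cnt <- data.frame(anchor = "P1", partner = "F3", type = "PD",
                    replicate = c("rep1", "rep2"), n = c(3L, 3L))
  called <- call_interactions(cnt, pr, fm, min_support = 3L)
  expect_equal(nrow(called), 1L)
  expect_equal(called$anchor_gene, "G1")
  expect_equal(called$chrom_b, "chrT")
  expect_equal(c(called$start_b, called$end_b), c(5000, 9000))

  cnt$n <- c(5L, 2L)   # fails in one replicate
  expect_equal(nrow(call_interactions(cnt, pr, fm, min_support = 3L)), 0L)
  # threshold floor: any support calls at min_support = 1
  expect_equal(nrow(call_interactions(cnt, pr, fm, min_support = 1L)), 1L)
  # a replicate absent from the counts table counts as zero
  expect_equal(nrow(call_interactions(cnt[1, ], pr, fm, min_support = 1L,
                                      replicates = c("rep1", "rep2"))), 0L)
})

test_that("called sets are nested as min_support rises", {
  w <- world()
  support <- count_support(w$filtered)
  key <- function(calls) paste(calls$anchor, calls$partner, calls$type)
  k_prev <- NULL
  for (t in c(3L, 4L, 5L)) {
    k <- key(call_interactions(support, w$pr, w$fm, min_support = t))
    if (!is.null(k_prev)) expect_true(all(k %in% k_prev))
    k_prev <- k
  }
})

test_that("distal-distal calling is restricted to called distal fragments", {
  fm <- digest_genome(genome_with_cuts(20000, c(1000, 5000, 9000, 13000)))
  tss <- data.frame(chrom = "chrT", tss = 2000, promoter_id = "P1",
                    gene_id = "G1")
  pr <- design_probe_targets(tss, fm)
  # PD calls naming fragments 3 and 4 as distal
  cnt <- data.frame(anchor = "P1", partner = rep(c("F3", "F4"), each = 2),
                    type = "PD", replicate = rep(c("rep1", "rep2"), 2),
                    n = 3L)
  pd <- call_interactions(cnt, pr, fm)
  raw <- function(f1, f2, rep_, n) {
    do.call(rbind, lapply(seq_len(n), function(i)
      data.frame(read_id = paste0(rep_, f1, f2, i), chrom1 = "chrT",
                 pos1 = 0L, strand1 = "+", chrom2 = "chrT", pos2 = 0L,
                 strand2 = "-", frag1 = f1, frag2 = f2,
                 validity_class = "valid", replicate = rep_)))
  }
  pairs <- rbind(raw(3L, 4L, "rep1", 3), raw(3L, 4L, "rep2", 4),
                 raw(3L, 5L, "rep1", 5), raw(3L, 5L, "rep2", 5))
  dd <- call_dd(pairs, pd, fm, replicates = c("rep1", "rep2"))
  expect_equal(nrow(dd), 1L)            # (3,5) ignored: 5 never a PD distal
  expect_equal(c(dd$anchor, dd$partner), c("F3", "F4"))
  expect_equal(dd$type, "DD")
  # support below threshold in one replicate: not called
  pairs2 <- rbind(raw(3L, 4L, "rep1", 3), raw(3L, 4L, "rep2", 2))
  expect_equal(nrow(call_dd(pairs2, pd, fm,
                            replicates = c("rep1", "rep2"))), 0L)
  # no PD calls: empty DD set
  expect_equal(nrow(call_dd(pairs, pd[0, ], fm,
                            replicates = c("rep1", "rep2"))), 0L)
})

test_that("closest-gene annotation uses fragment midpoints with a left tie-break", {
  tss <- data.frame(chrom = "chrT", tss = c(10000, 50000),
                    gene_id = c("A", "B"))
  calls <- make_calls("P1", "F7", "PD", chrom_a = "chrT", start_a = 9000L,
                      end_a = 9100L, chrom_b = "chrT", start_b = 19500L,
                      end_b = 20500L, distance = 11000,
                      anchor_gene = "A")   # distal midpoint 20000
  ann <- annotate_closest_gene(calls, tss)
  expect_equal(ann$closest_gene, "A")
  expect_true(ann$closest_gene_flag)
  calls$anchor_gene <- "B"
  expect_false(annotate_closest_gene(calls, tss)$closest_gene_flag)
  # exact tie at midpoint 30000: lower-coordinate TSS wins
  calls_tie <- make_calls("P1", "F7", "PD", chrom_a = "chrT",
                          start_a = 0L, end_a = 100L, chrom_b = "chrT",
                          start_b = 29500L, end_b = 30500L,
                          distance = 29950, anchor_gene = "A")
  expect_equal(annotate_closest_gene(calls_tie, tss)$closest_gene, "A")
  # trans calls stay unannotated
  calls_trans <- make_calls("P1", "F7", "PD", trans = TRUE, distance = NA)
  expect_true(is.na(annotate_closest_gene(calls_trans, tss)$closest_gene))
})

test_that("planted loops are recovered on simulated data", {
  w <- world()
  rec <- loop_recovery(w$calls, w$rd$truth)
  expect_gte(rec$precision, 0.9)
  expect_gte(rec$recall, 0.8)
})
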