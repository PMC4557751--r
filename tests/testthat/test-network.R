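test_that("network construction types nodes and edges and is idempotent", {
  pd <- make_calls("P1", "F1", "PD")
  net <- build_network(pd)
  expect_equal(igraph::vcount(net), 2L)
  expect_equal(igraph::ecount(net), 1L)
  expect_equal(igraph::E(net)$etype, "PE")
  expect_setequal(igraph::V(net)$type, c("promoter", "enhancer"))
  # PP call typed PP; duplicate input collapses to one edge
  pp <- rbind(make_calls("P1", "P2", "PP"), make_calls("P1", "P2", "PP"))
  class(pp) <- c("hicap_calls", "data.frame")
  net2 <- build_network(pp)
  expect_equal(igraph::ecount(net2), 1L)
  expect_equal(igraph::E(net2)$etype, "PP")
  expect_equal(igraph::E(net2)$weight, 12)   # 2 calls x (3+3) support
})

test_that("degree statistics match hand counts", {
  star <- do.call(rbind, lapply(1:5, function(i)
    make_calls("P1", paste0("F", i), "PD")))
  class(star) <- c("hicap_calls", "data.frame")
  ds <- degree_stats(build_network(star))
  expect_equal(ds$mean_enhancers_per_promoter, 5.0)
  expect_equal(ds$mean_promoters_per_enhancer, 1.0)
  # brute-force neighbor count on a random small graph
  set.seed(FIXTURE_SEED)
  calls <- random_typed_calls()
  net <- build_network(calls)
  ds2 <- degree_stats(net)
  pe <- calls[calls$type == "PD", ]
  for (e in names(ds2$enhancer_degree))
    expect_equal(unname(ds2$enhancer_degree[e]),
                 length(unique(pe$anchor[pe$partner == e])))
})

test_that("edge randomization preserves per-class degrees exactly", {
  set.seed(FIXTURE_SEED)
  calls <- random_typed_calls(n_p = 8L, n_e = 8L, n_edges = 24L)
  net <- build_network(calls)
  class_degrees <- function(g) {
    ed <- igraph::as_data_frame(g, "edges")
    lapply(split(ed, ed$etype),
           function(x) sort(table(c(x$from, x$to))))
  }
  bgs <- randomize_edges(net, n_rounds = 3L, seed = FIXTURE_SEED)
  for (bg in bgs) {
    expect_equal(class_degrees(bg), class_degrees(net))
    ed <- igraph::as_data_frame(bg, "edges")
    expect_false(any(ed$from == ed$to))                       # no loops
    expect_false(anyDuplicated(paste(pmin(ed$from, ed$to),
                                     pmax(ed$from, ed$to))) > 0)
    vt <- stats::setNames(igraph::V(bg)$type, igraph::V(bg)$name)
    pe <- ed[ed$etype == "PE", ]
    expect_true(all(vt[pe$from] != vt[pe$to]))                # typed edges
  }
  # determinism and single-edge classes unchanged
  expect_identical(
    igraph::as_data_frame(randomize_edges(net, 1L, seed = 7L)[[1]]),
    igraph::as_data_frame(randomize_edges(net, 1L, seed = 7L)[[1]]))
  single <- build_network(make_calls("P1", "P2", "PP"))
  same <- randomize_edges(single, 1L, seed = 1L)[[1]]
  expect_equal(igraph::as_data_frame(same, "edges")[, 1:2],
               igraph::as_data_frame(single, "edges")[, 1:2])
})

test_that("motif counts equal exhaustive enumeration on small graphs", {
  # promoters A,B joined to each other and both to enhancer E
  tri <- rbind(make_calls("PA", "PB", "PP"),
               make_calls("PA", "F1", "PD"),
               make_calls("PB", "F1", "PD"))
  class(tri) <- c("hicap_calls", "data.frame")
  m <- count_motifs(build_network(tri), n_background = 0L)
  got <- stats::setNames(m$observed, m$motif)
  expect_equal(unname(got[c("pp", "pe", "pep", "ppe_triangle")]),
               c(1, 2, 1, 1))
  # randomized instances vs brute-force oracle
  set.seed(FIXTURE_SEED + 1L)
  for (i in 1:5) {
    calls <- random_typed_calls(n_p = sample(3:6, 1), n_e = sample(3:6, 1),
                                n_edges = sample(8:16, 1))
    m <- count_motifs(build_network(calls), n_background = 0L)
    expect_equal(stats::setNames(m$observed, m$motif),
                 oracle_motifs(calls)[m$motif])
  }
  # empty network
  empty <- build_network(make_calls("P1", "F1", "PD")[0, ])
  expect_true(all(count_motifs(empty, n_background = 0L)$observed == 0))
})

test_that("motifs absent from every randomization get ~inf enrichment", {
  # with only 2 PE edges on one shared enhancer, rewiring cannot break the
  # p-p-e triangle: enrichment is a finite ratio of 1
  tri <- rbind(make_calls("PA", "PB", "PP"),
               make_calls("PA", "F1", "PD"),
               make_calls("PB", "F1", "PD"))
  class(tri) <- c("hicap_calls", "data.frame")
  m <- count_motifs(build_network(tri), n_background = 3L,
                    seed = FIXTURE_SEED)
  expect_equal(m$enrichment[m$motif == "ppe_triangle"], "1")
  # an enhancer 3-clique diluted in many disjoint EE edges essentially
  # never reassembles under degree-preserving rewiring: labelled ~inf
  ee <- rbind(make_calls("F01", "F02", "DD"),
              make_calls("F01", "F03", "DD"),
              make_calls("F02", "F03", "DD"),
              do.call(rbind, lapply(seq(4, 26, by = 2), function(i)
                make_calls(sprintf("F%02d", i), sprintf("F%02d", i + 1),
                           "DD"))))
  class(ee) <- c("hicap_calls", "data.frame")
  m2 <- count_motifs(build_network(ee), n_background = 5L,
                     seed = FIXTURE_SEED)
  expect_equal(m2$observed[m2$motif == "eee_clique"], 1)
  expect_equal(m2$enrichment[m2$motif == "eee_clique"], "~inf")
})

test_that("maximal cliques match brute force and igraph examples", {
  k4 <- do.call(rbind, lapply(utils::combn(paste0("P", 1:4), 2,
                                           simplify = FALSE),
                              function(x) make_calls(x[1], x[2], "PP")))
  class(k4) <- c("hicap_calls", "data.frame")
  expect_equal(max_cliques(build_network(k4), "promoter")$max_size, 4L)
  path <- rbind(make_calls("P1", "P2", "PP"), make_calls("P2", "P3", "PP"))
  class(path) <- c("hicap_calls", "data.frame")
  expect_equal(max_cliques(build_network(path), "promoter")$max_size, 2L)
  # random instances <= 12 nodes vs exhaustive subset search
  set.seed(FIXTURE_SEED + 2L)
  for (i in 1:5) {
    calls <- random_typed_calls(n_p = 6L, n_e = 6L, n_edges = 18L)
    for (ty in c("promoter", "enhancer")) {
      got <- max_cliques(build_network(calls), ty)
      want <- oracle_max_cliques(calls, ty)
      expect_equal(got$max_size, want$max_size)
      expect_setequal(vapply(got$cliques, paste, character(1),
                             collapse = ","),
                      vapply(want$cliques, paste, character(1),
                             collapse = ","))
    }
  }
})

test_that("same-TF enhancer subnetwork degree and empirical p behave", {
  # EE clique of 4 bound enhancers among 12 total
  ee <- do.call(rbind, lapply(utils::combn(paste0("F", 1:4), 2,
                                           simplify = FALSE), function(x)
    make_calls(x[1], x[2], "DD",
               chrom_b = "c1", start_b = 2000L, end_b = 2100L)))
  iso <- do.call(rbind, lapply(5:12, function(i)
    make_calls("P1", paste0("F", i), "PD",
               chrom_b = "c1", start_b = 5000L + i * 1000L,
               end_b = 5100L + i * 1000L)))
  calls <- rbind(ee, iso)
  class(calls) <- c("hicap_calls", "data.frame")
  net <- build_network(calls)
  # the clique members sit at [0,100) / [2000,2100); peaks cover them
  vert <- igraph::as_data_frame(net, "vertices")
  clique_nodes <- vert[vert$name %in% paste0("F", 1:4), ]
  peaks <- data.frame(chrom = clique_nodes$chrom,
                      start = clique_nodes$start, end = clique_nodes$end)
  res <- same_tf_degree(net, peaks, n_rand = 200L, seed = FIXTURE_SEED)
  expect_equal(res$mean_degree, 3.0)       # K4 internal degree
  expect_lte(res$p, 2 / 200)               # at/near the 1/n_rand floor
  # all enhancers bound: p = 1 (every random selection equals it)
  allpk <- vert[vert$type == "enhancer", c("chrom", "start", "end")]
  res2 <- same_tf_degree(net, allpk, n_rand = 50L, seed = 1L)
  expect_equal(res2$p, 1.0)
  # < 2 bound enhancers: undefined
  res3 <- same_tf_degree(net, peaks[0, ], n_rand = 10L)
  expect_false(res3$defined)
})

test_that("GO pair sharing counts, floors p and BH-adjusts", {
  # gA-gB connected by PP and by sharing enhancer F1
  calls <- rbind(
    make_calls("P1", "P2", "PP", anchor_gene = "gA", partner_gene = "gB"),
    make_calls("P1", "F1", "PD", anchor_gene = "gA"),
    make_calls("P2", "F1", "PD", anchor_gene = "gB"),
    make_calls("P3", "F2", "PD", anchor_gene = "gC"),
    make_calls("P4", "F3", "PD", anchor_gene = "gD"),
    make_calls("P5", "F4", "PD", anchor_gene = "gE"))
  class(calls) <- c("hicap_calls", "data.frame")
  net <- build_network(calls)
  go <- data.frame(gene_id = c("gA", "gB", "gC", "gD"),
                   term = c("T1", "T1", "T2", "T2"))
  res <- go_pair_sharing(net, go, n_rand = 100L, seed = FIXTURE_SEED)
  res <- res[order(res$term), ]
  expect_equal(res$pair_count, c(1L, 0L))
  # T2 annotates no connected pair: p = 1; and with the "observed - 1"
  # convention a single-pair term is never significant either
  expect_equal(res$p[res$term == "T2"], 1.0)
  expect_equal(res$p[res$term == "T1"], 1.0)
  expect_true(all(res$p >= 1 / 100 & res$p <= 1))
  expect_equal(res$fdr, stats::p.adjust(res$p, "BH"))
})

test_that("support vs shared enhancers combines group Wilcoxon tests", {
  # identical z in all groups: Stouffer returns that z
  st <- hicapr:::stouffer(rep(1.7, 6))
  expect_equal(st$z, 1.7 * 6 / sqrt(6))
  expect_equal(hicapr:::stouffer(c(2.2))$z, 2.2)
  # one eligible group: combined p equals that group's two-tailed p
  set.seed(FIXTURE_SEED + 3L)
  pp <- do.call(rbind, lapply(1:20, function(i)
    make_calls(sprintf("P%02da", i), sprintf("P%02db", i), "PP",
               distance = 1500,
               supp_rep1 = if (i <= 10) 3L else 30L, supp_rep2 = 3L)))
  # second half shares an enhancer; first half gets disjoint enhancers so
  # every promoter pair lands in the same degree-sum group
  pe_shared <- do.call(rbind, lapply(11:20, function(i)
    rbind(make_calls(sprintf("P%02da", i), sprintf("F%02d", i), "PD"),
          make_calls(sprintf("P%02db", i), sprintf("F%02d", i), "PD"))))
  pe_lone <- do.call(rbind, lapply(1:10, function(i)
    rbind(make_calls(sprintf("P%02da", i), sprintf("FA%02d", i), "PD"),
          make_calls(sprintf("P%02db", i), sprintf("FB%02d", i), "PD"))))
  calls <- rbind(pp, pe_shared, pe_lone)
  class(calls) <- c("hicap_calls", "data.frame")
  res <- support_vs_shared_enhancers(calls)
  expect_equal(nrow(res$groups), 1L)
  expect_equal(res$combined_p,
               2 * stats::pnorm(-abs(res$groups$z[1])))
  expect_gt(res$groups$z[1], 0)   # higher support with shared enhancer
})
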