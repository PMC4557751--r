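# Shared fixtures and independent oracles. The fixture world is built once
# per test run (memoised) at a scale small enough to keep the suite fast.
# Seed 20150701 everywhere; chosen up front, never revisited.

FIXTURE_SEED <- 20150701L

# small simulated world shared across module tests
world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(genome_length = 4e6, n_chrom = 2L,
                        n_promoters = 200L, n_planted_loops = 150L,
                        n_planted_pp = 20L, n_planted_ee = 20L,
                        pairs_per_replicate = 1e5)
      sim <- simulate_genome(cfg, seed = FIXTURE_SEED)
      fm <- digest_genome(sim$genome)
      pr <- design_probe_targets(sim$tss_table, fm)
      rd <- simulate_reads(cfg, sim, fm, pr, seed = FIXTURE_SEED + 1L)
      classified <- classify_pairs(dedupe_pairs(pair_ends(rd$ends)), fm)
      filtered <- on_target_filter(classified, pr)
      calls <- call_interactions(count_support(filtered), pr, fm)
      dd <- call_dd(classified, calls, fm)
      om <- simulate_omics(cfg, sim, rd$truth, fm,
                           seed = FIXTURE_SEED + 2L)
      cache <<- list(cfg = cfg, sim = sim, fm = fm, pr = pr, rd = rd,
                     classified = classified, filtered = filtered,
                     calls = calls, dd = dd, om = om)
    }
    cache
  }
})

# PD + PP + DD calls in one table
all_calls <- function(w) {
  out <- rbind(as.data.frame(w$calls), as.data.frame(w$dd))
  attr(out, "replicates") <- attr(w$calls, "replicates")
  class(out) <- c("hicap_calls", "data.frame")
  out
}

# a genome string with GATC planted at exact 0-based positions
genome_with_cuts <- function(len, cuts, base = "A") {
  s <- rep(base, len)
  for (p in cuts) s[(p + 1):(p + 4)] <- c("G", "A", "T", "C")
  stats::setNames(paste(s, collapse = ""), "chrT")
}

# hand-built hicap_calls row(s); defaults give a minimal valid record
make_calls <- function(anchor, partner, type,
                       chrom_a = "c1", start_a = 0L, end_a = 100L,
                       chrom_b = "c1", start_b = 1000L, end_b = 1100L,
                       distance = 1000, trans = FALSE,
                       anchor_gene = NA_character_,
                       partner_gene = NA_character_,
                       supp_rep1 = 3L, supp_rep2 = 3L) {
  out <- data.frame(anchor = anchor, anchor_gene = anchor_gene,
                    partner = partner, partner_gene = partner_gene,
                    type = type, chrom_a = chrom_a, start_a = start_a,
                    end_a = end_a, chrom_b = chrom_b, start_b = start_b,
                    end_b = end_b, distance = distance, trans = trans,
                    supp_rep1 = supp_rep1, supp_rep2 = supp_rep2,
                    stringsAsFactors = FALSE)
  attr(out, "replicates") <- c("rep1", "rep2")
  class(out) <- c("hicap_calls", "data.frame")
  out
}

# random typed interaction table over <= 12 nodes, for oracle comparisons
random_typed_calls <- function(n_p = 6L, n_e = 6L, n_edges = 14L) {
  np <- sprintf("P%02d", seq_len(n_p)); ne <- sprintf("F%02d", seq_len(n_e))
  rows <- list()
  for (i in seq_len(n_edges)) {
    ty <- sample(c("PD", "PP", "DD"), 1L)
    if (ty == "PD") { a <- sample(np, 1L); b <- sample(ne, 1L) }
    else if (ty == "PP") { x <- sample(np, 2L); a <- min(x); b <- max(x) }
    else { x <- sample(ne, 2L); a <- min(x); b <- max(x) }
    rows[[i]] <- make_calls(a, b, ty)
  }
  out <- unique(data.table::rbindlist(rows))
  out <- as.data.frame(out[out$anchor != out$partner, ])
  attr(out, "replicates") <- c("rep1", "rep2")
  class(out) <- c("hicap_calls", "data.frame")
  out
}

# hicap_calls synthesized directly from planted truth (PD loops), for
# tests that probe downstream statistics independently of the caller
truth_calls <- function(truth, probes, fragmap) {
  pr <- as.data.frame(hicapr:::promoter_regions(probes))
  m <- match(truth$loops$promoter_id, pr$promoter_id)
  fi <- match(truth$loops$frag_id, fragmap$frag_id)
  mid_a <- (pr$start[m] + pr$end[m]) / 2
  mid_b <- (fragmap$start[fi] + fragmap$end[fi]) / 2
  out <- data.frame(
    anchor = truth$loops$promoter_id, anchor_gene = pr$gene_id[m],
    partner = paste0("F", truth$loops$frag_id),
    partner_gene = NA_character_, type = "PD",
    chrom_a = pr$chrom[m], start_a = pr$start[m], end_a = pr$end[m],
    chrom_b = fragmap$chrom[fi], start_b = fragmap$start[fi],
    end_b = fragmap$end[fi],
    distance = abs(mid_b - mid_a),
    trans = pr$chrom[m] != fragmap$chrom[fi],
    supp_rep1 = 3L, supp_rep2 = 3L, stringsAsFactors = FALSE)
  attr(out, "replicates") <- c("rep1", "rep2")
  class(out) <- c("hicap_calls", "data.frame")
  out
}

# ---- independent oracles ------------------------------------------------

# adjacency matrix + type vector from a calls table
calls_adjacency <- function(calls) {
  nodes <- sort(unique(c(calls$anchor, calls$partner)))
  ty <- ifelse(startsWith(nodes, "P"), "p", "e")
  A <- matrix(FALSE, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(calls))) {
    A[calls$anchor[i], calls$partner[i]] <- TRUE
    A[calls$partner[i], calls$anchor[i]] <- TRUE
  }
  list(A = A, type = stats::setNames(ty, nodes))
}

# brute-force motif counts by exhaustive subset enumeration
oracle_motifs <- function(calls) {
  ad <- calls_adjacency(calls); A <- ad$A; ty <- ad$type
  nodes <- rownames(A)
  P <- nodes[ty == "p"]; E <- nodes[ty == "e"]
  cnt <- c(pp = 0, pe = 0, ee = 0, pep = 0, epe = 0, ppe_triangle = 0,
           ppp_clique = 0, eee_clique = 0)
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i < j && A[i, j]) {
      k <- paste0(sort(c(ty[i], ty[j])), collapse = "")
      key <- c(pp = "pp", ep = "pe", pe = "pe", ee = "ee")[k]
      cnt[key] <- cnt[key] + 1
    }
  }
  if (length(P) >= 2) for (p1 in P) for (p2 in P) if (p1 < p2) {
    for (e in E) if (A[p1, e] && A[p2, e]) {
      cnt["pep"] <- cnt["pep"] + 1
      if (A[p1, p2]) cnt["ppe_triangle"] <- cnt["ppe_triangle"] + 1
    }
    if (A[p1, p2]) for (p3 in P) if (p3 > p2 && A[p1, p3] && A[p2, p3])
      cnt["ppp_clique"] <- cnt["ppp_clique"] + 1
  }
  if (length(E) >= 2) for (e1 in E) for (e2 in E) if (e1 < e2) {
    for (p in P) if (A[e1, p] && A[e2, p])
      cnt["epe"] <- cnt["epe"] + 1
    if (A[e1, e2]) for (e3 in E) if (e3 > e2 && A[e1, e3] && A[e2, e3])
      cnt["eee_clique"] <- cnt["eee_clique"] + 1
  }
  cnt
}

# brute-force maximal cliques among one node type (exhaustive subsets)
oracle_max_cliques <- function(calls, node_type = "promoter") {
  ad <- calls_adjacency(calls); A <- ad$A; ty <- ad$type
  want <- if (node_type == "promoter") "p" else "e"
  nodes <- rownames(A)[ty == want]
  n <- length(nodes)
  if (n == 0) return(list(cliques = list(), max_size = 0L))
  is_clique <- function(s) {
    if (length(s) < 2) return(FALSE)
    all(A[s, s][upper.tri(diag(length(s)))])
  }
  subsets <- lapply(seq_len(2^n - 1), function(m)
    nodes[bitwAnd(m, 2^(seq_len(n) - 1)) > 0])
  cliques <- Filter(is_clique, subsets)
  maximal <- Filter(function(s) {
    !any(vapply(setdiff(nodes, s), function(v)
      all(A[v, s]), logical(1)))
  }, cliques)
  maximal <- lapply(maximal, sort)
  list(cliques = maximal[order(vapply(maximal, paste, character(1),
                                      collapse = ","))],
       max_size = if (length(maximal)) max(lengths(maximal)) else 0L)
}
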