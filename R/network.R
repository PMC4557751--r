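#' Build a typed regulatory network from interaction calls
#'
#' One node per promoter or distal (enhancer candidate) region, one
#' undirected edge per call, typed `PP`, `PE` (promoter-distal) or `EE`
#' (distal-distal), weighted by summed read support over replicates and
#' carrying the interaction distance. Duplicate calls collapse to a single
#' edge; self-loops cannot arise (anchor != partner by construction).
#'
#' @param calls a `hicap_calls` data.frame (PD, PP and/or DD calls).
#' @return an `igraph` graph with vertex attributes `type`
#'   (`"promoter"`/`"enhancer"`), `gene`, `chrom`, `start`, `end`, and edge
#'   attributes `etype`, `weight`, `distance`.
#' @export
build_network <- function(calls) {
  supp_cols <- grep("^supp_", names(calls), value = TRUE)
  w <- if (length(supp_cols)) rowSums(calls[, supp_cols, drop = FALSE])
       else rep(1, nrow(calls))
  etype <- c(PD = "PE", PP = "PP", DD = "EE")[calls$type]

  vert <- unique(rbind(
    data.frame(name = calls$anchor,
               type = ifelse(calls$type == "DD", "enhancer", "promoter"),
               gene = calls$anchor_gene, chrom = calls$chrom_a,
               start = calls$start_a, end = calls$end_a,
               stringsAsFactors = FALSE),
    data.frame(name = calls$partner,
               type = ifelse(calls$type == "PP", "promoter", "enhancer"),
               gene = calls$partner_gene, chrom = calls$chrom_b,
               start = calls$start_b, end = calls$end_b,
               stringsAsFactors = FALSE)
  ))
  vert <- vert[!duplicated(vert$name), , drop = FALSE]

  ed <- data.table::data.table(
    a = pmin(calls$anchor, calls$partner),
    b = pmax(calls$anchor, calls$partner),
    etype = etype, weight = w, distance = calls$distance)
  ed <- ed[, .(etype = etype[1L], weight = sum(weight),
               distance = distance[1L]), by = .(a, b)]
  g <- igraph::graph_from_data_frame(
    as.data.frame(ed), directed = FALSE, vertices = vert)
  g
}

#' Per-type degree statistics
#'
#' For every enhancer node, the number of distinct promoter neighbors, and
#' for every promoter node, the number of distinct enhancer neighbors, with
#' their means (the "promoters per distal region" and "distal regions per
#' promoter" summary).
#'
#' @param net a network from [build_network()].
#' @return list: `enhancer_degree`, `promoter_degree` (named integer
#'   vectors), `mean_promoters_per_enhancer`, `mean_enhancers_per_promoter`.
#' @export
degree_stats <- function(net) {
  vt <- igraph::V(net)$type
  names(vt) <- igraph::V(net)$name
  ed <- igraph::as_data_frame(net, what = "edges")
  pe <- ed[ed$etype == "PE", , drop = FALSE]
  p_side <- ifelse(vt[pe$from] == "promoter", pe$from, pe$to)
  e_side <- ifelse(vt[pe$from] == "promoter", pe$to, pe$from)
  enh <- names(vt)[vt == "enhancer"]; pro <- names(vt)[vt == "promoter"]
  e_deg <- stats::setNames(integer(length(enh)), enh)
  p_deg <- stats::setNames(integer(length(pro)), pro)
  if (nrow(pe)) {
    te <- table(e_side); e_deg[names(te)] <- as.integer(te)
    tp <- table(p_side); p_deg[names(tp)] <- as.integer(tp)
  }
  list(enhancer_degree = e_deg, promoter_degree = p_deg,
       mean_promoters_per_enhancer =
         if (length(e_deg)) mean(e_deg) else NA_real_,
       mean_enhancers_per_promoter =
         if (length(p_deg)) mean(p_deg) else NA_real_)
}

## degree-preserving double-edge-swap on an edge matrix (vertex name pairs).
## bipartite = TRUE keeps column roles (e.g. promoter side / enhancer side)
## fixed, which preserves endpoint types for PE edges. `forbidden` is a
## character set of keys that must not be created (edges of other classes).
swap_edges <- function(ed, bipartite, n_iter = NULL) {
  m <- nrow(ed)
  if (m < 2L) return(ed)
  if (is.null(n_iter)) n_iter <- 10L * m
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  have <- new.env(hash = TRUE, parent = emptyenv())
  for (k in key(ed[, 1L], ed[, 2L])) assign(k, TRUE, envir = have)
  for (it in seq_len(n_iter)) {
    ij <- sample.int(m, 2L)
    i <- ij[1L]; j <- ij[2L]
    a1 <- ed[i, 1L]; b1 <- ed[i, 2L]
    a2 <- ed[j, 1L]; b2 <- ed[j, 2L]
    if (!bipartite && stats::runif(1) < 0.5) { tmp <- a2; a2 <- b2; b2 <- tmp }
    ## propose (a1,b2), (a2,b1)
    if (a1 == b2 || a2 == b1) next
    k1 <- key(a1, b2); k2 <- key(a2, b1)
    if (k1 == k2 || exists(k1, envir = have) || exists(k2, envir = have))
      next
    rm(list = c(key(a1, b1), key(a2, b2)), envir = have)
    assign(k1, TRUE, envir = have); assign(k2, TRUE, envir = have)
    ed[i, 1L] <- a1; ed[i, 2L] <- b2
    ed[j, 1L] <- a2; ed[j, 2L] <- b1
  }
  ed
}

#' Degree-preserving randomization of the network
#'
#' Rewires the PP, PE and EE edge classes separately by repeated double-edge
#' swaps, preserving every node's degree within each class exactly, without
#' creating self-loops or duplicate edges. A class with fewer than two edges
#' is returned unchanged. Used as the null model for motif enrichment.
#'
#' @param net a network from [build_network()].
#' @param n_rounds number of independent randomized networks (default 5).
#' @param seed optional integer seed (reproducible).
#' @param joint rewire all edges as a single pool ignoring the class split
#'   (the null used for the GO pair-sharing test). Default FALSE.
#' @return list of `n_rounds` igraph networks with identical vertices.
#' @export
randomize_edges <- function(net, n_rounds = 5L, seed = NULL, joint = FALSE) {
  ed <- igraph::as_data_frame(net, what = "edges")
  vert <- igraph::as_data_frame(net, what = "vertices")
  vt <- stats::setNames(vert$type, vert$name)
  with_seed_if(seed, {
    lapply(seq_len(n_rounds), function(r) {
      new_ed <- ed
      if (joint) {
        m <- as.matrix(ed[, c("from", "to")])
        m <- swap_edges(m, bipartite = FALSE)
        new_ed$from <- m[, 1L]; new_ed$to <- m[, 2L]
      } else {
        for (cl in unique(ed$etype)) {
          ix <- which(ed$etype == cl)
          if (length(ix) < 2L) next
          m <- as.matrix(ed[ix, c("from", "to")])
          if (cl == "PE") {   # orient promoter side first, keep roles fixed
            flip <- vt[m[, 1L]] != "promoter"
            m[flip, ] <- m[flip, c(2L, 1L)]
          }
          m <- swap_edges(m, bipartite = (cl == "PE"))
          new_ed$from[ix] <- m[, 1L]; new_ed$to[ix] <- m[, 2L]
        }
      }
      igraph::graph_from_data_frame(new_ed, directed = FALSE,
                                    vertices = vert)
    })
  })
}

## adjacency sets by class, on vertex names
adjacency_sets <- function(net) {
  vt <- stats::setNames(igraph::V(net)$type, igraph::V(net)$name)
  ed <- igraph::as_data_frame(net, what = "edges")
  mk <- function(from, to) {
    s <- split(c(to, from), c(from, to))
    lapply(s, unique)
  }
  pp <- ed[vt[ed$from] == "promoter" & vt[ed$to] == "promoter", ]
  ee <- ed[vt[ed$from] == "enhancer" & vt[ed$to] == "enhancer", ]
  pe <- ed[vt[ed$from] != vt[ed$to], ]
  p_of_pe <- ifelse(vt[pe$from] == "promoter", pe$from, pe$to)
  e_of_pe <- ifelse(vt[pe$from] == "promoter", pe$to, pe$from)
  list(
    vt = vt,
    ppN = mk(pp$from, pp$to),
    eeN = mk(ee$from, ee$to),
    peN_p = lapply(split(e_of_pe, p_of_pe), unique),  # promoter -> enhancers
    peN_e = lapply(split(p_of_pe, e_of_pe), unique),  # enhancer -> promoters
    n_pp = nrow(pp), n_ee = nrow(ee), n_pe = nrow(pe)
  )
}

## one network's motif counts + participating node sets
motif_census <- function(net) {
  A <- adjacency_sets(net)
  res <- list()
  add <- function(id, count, proms, enhs)
    res[[id]] <<- list(count = count,
                       promoters = unique(proms), enhancers = unique(enhs))
  pp_nodes <- names(A$ppN); ee_nodes <- names(A$eeN)
  add("pp", A$n_pp, pp_nodes[lengths(A$ppN[pp_nodes]) > 0], character())
  add("pe", A$n_pe, names(A$peN_p), names(A$peN_e))
  add("ee", A$n_ee, character(), ee_nodes[lengths(A$eeN[ee_nodes]) > 0])
  ## p-e-p: two promoters sharing an enhancer
  deg2e <- names(A$peN_e)[lengths(A$peN_e) >= 2L]
  add("pep", sum(choose(lengths(A$peN_e[deg2e]), 2)),
      unlist(A$peN_e[deg2e]), deg2e)
  ## e-p-e: two enhancers sharing a promoter
  deg2p <- names(A$peN_p)[lengths(A$peN_p) >= 2L]
  add("epe", sum(choose(lengths(A$peN_p[deg2p]), 2)),
      deg2p, unlist(A$peN_p[deg2p]))
  ## p-p-e triangle: PP edge whose promoters share an enhancer
  cnt <- 0L; tp <- character(); te <- character()
  for (p1 in names(A$ppN)) for (p2 in A$ppN[[p1]]) {
    if (p1 < p2) {
      common <- intersect(A$peN_p[[p1]], A$peN_p[[p2]])
      if (length(common)) {
        cnt <- cnt + length(common)
        tp <- c(tp, p1, p2); te <- c(te, common)
      }
    }
  }
  add("ppe_triangle", cnt, tp, te)
  ## 3-cliques within one type
  clique3 <- function(adj) {
    cnt <- 0L; nodes <- character()
    for (a in names(adj)) for (b in adj[[a]]) {
      if (a < b) {
        common <- intersect(adj[[a]], adj[[b]])
        common <- common[common > b]   # ordered triple a < b < c
        if (length(common)) {
          cnt <- cnt + length(common)
          nodes <- c(nodes, a, b, common)
        }
      }
    }
    list(count = cnt, nodes = unique(nodes))
  }
  c3p <- clique3(A$ppN); c3e <- clique3(A$eeN)
  add("ppp_clique", c3p$count, c3p$nodes, character())
  add("eee_clique", c3e$count, character(), c3e$nodes)
  res
}

#' Count typed interaction motifs, with randomized-background enrichment
#'
#' Counts embeddings (up to automorphism) of the default motif catalog:
#' `pp`, `pe`, `ee` edges; `pep` and `epe` sharing paths; the `ppe_triangle`
#' (two interacting promoters sharing an enhancer); and same-type 3-cliques
#' `ppp_clique` / `eee_clique`. Subgraph embeddings are counted whether or
#' not additional edges are present (non-induced). Enrichment is
#' observed / mean over degree-preserving randomizations; motifs absent from
#' every randomization but observed get `"~inf"`.
#'
#' @param net a network from [build_network()].
#' @param motifs subset of motif ids to report (default: all).
#' @param n_background number of degree-preserving randomizations for the
#'   enrichment column (default 5; 0 disables the background).
#' @param seed optional integer seed for the randomizations.
#' @return data.frame: `motif`, `observed`, `unique_promoters`,
#'   `unique_enhancers`, and (with background) `background_mean`,
#'   `enrichment` (character; ratio, `"~inf"`, or `NA`).
#' @export
count_motifs <- function(net, motifs = NULL, n_background = 5L, seed = NULL) {
  obs <- motif_census(net)
  ids <- names(obs)
  if (!is.null(motifs)) ids <- intersect(ids, motifs)
  out <- data.frame(
    motif = ids,
    observed = vapply(obs[ids], `[[`, numeric(1), "count"),
    unique_promoters = vapply(obs[ids], function(z) length(z$promoters),
                              integer(1)),
    unique_enhancers = vapply(obs[ids], function(z) length(z$enhancers),
                              integer(1)),
    stringsAsFactors = FALSE
  )
  if (n_background > 0L) {
    bgs <- randomize_edges(net, n_rounds = n_background, seed = seed)
    bgc <- vapply(bgs, function(g)
      vapply(motif_census(g)[ids], `[[`, numeric(1), "count"),
      numeric(length(ids)))
    bgm <- if (is.matrix(bgc)) rowMeans(bgc) else mean(bgc)
    out$background_mean <- bgm
    out$enrichment <- ifelse(
      bgm > 0, format(out$observed / bgm, digits = 4, trim = TRUE),
      ifelse(out$observed > 0, "~inf", NA))
  }
  rownames(out) <- NULL
  out
}

#' Maximal cliques among nodes of one type
#'
#' All maximal cliques of the subgraph induced on promoter (or enhancer)
#' nodes and their same-type edges, and the size of the largest.
#'
#' @param net a network from [build_network()].
#' @param node_type `"promoter"` or `"enhancer"`.
#' @param min_size smallest clique size to report (default 2).
#' @return list: `cliques` (list of node-name vectors), `max_size`.
#' @export
max_cliques <- function(net, node_type = c("promoter", "enhancer"),
                        min_size = 2L) {
  node_type <- match.arg(node_type)
  keep <- igraph::V(net)[igraph::V(net)$type == node_type]
  sub <- igraph::induced_subgraph(net, keep)
  cl <- igraph::max_cliques(sub, min = min_size)
  cl <- lapply(cl, function(v) sort(igraph::V(sub)$name[as.integer(v)]))
  list(cliques = cl,
       max_size = if (length(cl)) max(lengths(cl)) else 0L)
}

#' Mean degree of same-TF enhancer subnetworks
#'
#' Restricts the enhancer-enhancer graph to enhancer nodes bound by a given
#' TF (overlap with its peaks) and computes the mean within-subnetwork
#' degree, with an empirical p-value against random enhancer-node selections
#' of the same size (fraction of selections with mean degree at least the
#' observed; floored at `1/n_rand`).
#'
#' @param net a network from [build_network()] (enhancer vertices must carry
#'   `chrom`/`start`/`end`).
#' @param tf_peaks data.frame of the TF's binding sites (`chrom`, `start`,
#'   `end`).
#' @param n_rand number of random selections (default 1000).
#' @param seed optional integer seed.
#' @return list: `n_bound`, `mean_degree`, `p` (`NA` with < 2 bound
#'   enhancers, flagged via `defined = FALSE`).
#' @export
same_tf_degree <- function(net, tf_peaks, n_rand = 1000L, seed = NULL) {
  vert <- igraph::as_data_frame(net, what = "vertices")
  enh <- vert[vert$type == "enhancer", , drop = FALSE]
  bound <- enh$name[interval_overlap_any(enh, tf_peaks)]
  if (length(bound) < 2L)
    return(list(n_bound = length(bound), mean_degree = NA_real_,
                p = NA_real_, defined = FALSE))
  A <- adjacency_sets(net)
  mean_deg <- function(sel) {
    mean(vapply(sel, function(v) {
      nb <- A$eeN[[v]]
      if (is.null(nb)) 0L else sum(nb %in% sel)
    }, integer(1)))
  }
  obs <- mean_deg(bound)
  hits <- with_seed_if(seed, {
    sum(vapply(seq_len(n_rand), function(i)
      mean_deg(sample(enh$name, length(bound))) >= obs, logical(1)))
  })
  list(n_bound = length(bound), mean_degree = obs,
       p = max(hits / n_rand, 1 / n_rand), defined = TRUE)
}

## gene pairs connected by PP edges or promoter-enhancer-promoter sharing
connected_gene_pairs <- function(net) {
  A <- adjacency_sets(net)
  vert <- igraph::as_data_frame(net, what = "vertices")
  gene <- stats::setNames(vert$gene, vert$name)
  pairs <- character(0)
  for (p1 in names(A$ppN)) for (p2 in A$ppN[[p1]]) {
    if (p1 < p2 && !is.na(gene[p1]) && !is.na(gene[p2]) &&
        gene[p1] != gene[p2])
      pairs <- c(pairs, paste(sort(c(gene[p1], gene[p2])), collapse = "|"))
  }
  for (e in names(A$peN_e)) {
    ps <- A$peN_e[[e]]
    ps <- ps[A$vt[ps] == "promoter" & !is.na(gene[ps])]
    if (length(ps) >= 2L) {
      cmb <- utils::combn(sort(ps), 2L)
      g1 <- gene[cmb[1L, ]]; g2 <- gene[cmb[2L, ]]
      keep <- g1 != g2
      pairs <- c(pairs, paste(pmin(g1, g2)[keep], pmax(g1, g2)[keep],
                              sep = "|"))
    }
  }
  unique(pairs)
}

#' GO-term sharing among connected gene pairs
#'
#' For each GO term, counts the gene pairs that are both annotated with the
#' term and connected by a promoter-promoter interaction or through a shared
#' enhancer (promoter-enhancer-promoter). Significance by joint
#' degree-preserving randomization of all interactions: p = (number of
#' randomizations with at least `observed - 1` such pairs) / `n_rand`,
#' floored at `1/n_rand`; Benjamini-Hochberg adjusted across terms.
#'
#' @param net a network from [build_network()] (promoter vertices must carry
#'   `gene`).
#' @param go_table data.frame with columns `gene_id`, `term`.
#' @param n_rand number of randomizations (default 1000).
#' @param seed optional integer seed.
#' @return data.frame: `term`, `pair_count`, `p`, `fdr`.
#' @export
go_pair_sharing <- function(net, go_table, n_rand = 1000L, seed = NULL) {
  terms <- lapply(split(go_table$gene_id, go_table$term), unique)
  count_terms <- function(pairs) {
    if (length(pairs) == 0L)
      return(stats::setNames(integer(length(terms)), names(terms)))
    gs <- strsplit(pairs, "|", fixed = TRUE)
    g1 <- vapply(gs, `[`, character(1), 1L)
    g2 <- vapply(gs, `[`, character(1), 2L)
    vapply(terms, function(tg) sum(g1 %in% tg & g2 %in% tg), integer(1))
  }
  obs <- count_terms(connected_gene_pairs(net))
  rand_counts <- with_seed_if(seed, {
    bgs <- randomize_edges(net, n_rounds = n_rand, seed = NULL, joint = TRUE)
    vapply(bgs, function(g) count_terms(connected_gene_pairs(g)),
           integer(length(terms)))
  })
  rand_counts <- matrix(rand_counts, nrow = length(terms))
  p <- vapply(seq_along(terms), function(i)
    max(sum(rand_counts[i, ] >= obs[i] - 1L) / n_rand, 1 / n_rand),
    numeric(1))
  data.frame(term = names(terms), pair_count = as.integer(obs), p = p,
             fdr = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read support of promoter pairs vs number of shared enhancers
#'
#' Tests whether promoter-promoter interactions additionally sharing
#' enhancers have higher read-pair support. Interactions are grouped by
#' distance (log2 bins 1000-1999, 2000-3999, ..., 64000-127999 bp) and by
#' the sum of the two promoter nodes' degrees (2, 3, ..., 19, with >= 20
#' pooled); within each group a one-tailed Wilcoxon rank-sum test compares
#' support between 0 vs 1 and 1 vs 2+ shared enhancers, and the per-group
#' z-scores are combined by Stouffer's method into a two-tailed p.
#'
#' @param calls a `hicap_calls` set containing the PP calls and the PE
#'   (`PD`) calls used to count shared enhancers and node degrees.
#' @param min_per_stratum minimum observations per stratum for a group test
#'   (default 2; smaller groups are skipped and logged in the output).
#' @return list: `groups` (one row per performed test), `combined_z`,
#'   `combined_p`, `n_skipped`.
#' @export
support_vs_shared_enhancers <- function(calls, min_per_stratum = 2L) {
  net <- build_network(calls)
  A <- adjacency_sets(net)
  deg <- igraph::degree(net)
  supp_cols <- grep("^supp_", names(calls), value = TRUE)
  pp <- calls[calls$type == "PP" & !calls$trans, , drop = FALSE]
  if (nrow(pp) == 0L) stop("no cis promoter-promoter calls")
  support <- rowSums(pp[, supp_cols, drop = FALSE])
  shared <- mapply(function(a, b) {
    length(intersect(A$peN_p[[a]], A$peN_p[[b]]))
  }, pp$anchor, pp$partner)
  degsum <- deg[pp$anchor] + deg[pp$partner]
  degsum_g <- ifelse(degsum >= 20, "20+", as.character(degsum))
  bin <- cut(pp$distance, breaks = c(1000 * 2^(0:7)), right = FALSE)

  strat <- ifelse(shared == 0L, "s0", ifelse(shared == 1L, "s1", "s2"))
  rows <- list(); zs <- numeric(0); skipped <- 0L
  for (b in levels(bin)) for (d in unique(degsum_g)) {
    gi <- which(!is.na(bin) & bin == b & degsum_g == d)
    if (length(gi) == 0L) next
    for (cmp in list(c("s0", "s1"), c("s1", "s2"))) {
      lo <- support[gi][strat[gi] == cmp[1L]]
      hi <- support[gi][strat[gi] == cmp[2L]]
      if (length(lo) < min_per_stratum || length(hi) < min_per_stratum) {
        skipped <- skipped + 1L
        next
      }
      p1 <- suppressWarnings(
        stats::wilcox.test(hi, lo, alternative = "greater")$p.value)
      z <- stats::qnorm(1 - min(max(p1, 1e-15), 1 - 1e-15))
      zs <- c(zs, z)
      rows[[length(rows) + 1L]] <- data.frame(
        bin = b, degree_sum = d, comparison = paste(cmp, collapse = "_vs_"),
        n_low = length(lo), n_high = length(hi), p_one_sided = p1, z = z,
        stringsAsFactors = FALSE)
    }
  }
  if (length(zs) == 0L)
    return(list(groups = NULL, combined_z = NA_real_, combined_p = NA_real_,
                n_skipped = skipped))
  st <- stouffer(zs)
  list(groups = do.call(rbind, rows), combined_z = st$z,
       combined_p = st$p_two_sided, n_skipped = skipped)
}
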