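#' Differentially expressed genes after a TF perturbation
#'
#' Selects genes with `fdr <= fdr_max` and fold change strictly greater than
#' `fc_min` (the usual FDR <= 0.05, FC > 1.5 rule; a gene at exactly
#' FC = 1.5 is excluded).
#'
#' @param de_table data.frame with columns `gene_id`, `fold_change`, `fdr`.
#' @param fdr_max maximum FDR (default 0.05).
#' @param fc_min fold-change threshold, strict (default 1.5).
#' @return character vector of gene ids.
#' @export
de_genes <- function(de_table, fdr_max = 0.05, fc_min = 1.5) {
  stopifnot(all(c("gene_id", "fold_change", "fdr") %in% names(de_table)))
  unique(de_table$gene_id[de_table$fdr <= fdr_max &
                            de_table$fold_change > fc_min])
}

#' Closest gene to each TF binding site
#'
#' For each peak, the gene whose TSS is nearest to the peak midpoint (ties
#' broken toward the lower-coordinate TSS). Peaks on chromosomes without any
#' TSS are unassigned (`NA`).
#'
#' @param tfbs data.frame of binding sites (`chrom`, `start`, `end`).
#' @param tss_table data.frame with `chrom`, `tss`, `gene_id`.
#' @return data.frame `peak` (row index), `chrom`, `midpoint`, `gene_id`.
#'   The deduplicated gene set is `unique(na.omit(out$gene_id))`.
#' @export
closest_genes <- function(tfbs, tss_table) {
  mid <- floor((tfbs$start + tfbs$end) / 2)
  data.frame(peak = seq_len(nrow(tfbs)), chrom = tfbs$chrom, midpoint = mid,
             gene_id = nearest_tss_gene(tfbs$chrom, mid, tss_table),
             stringsAsFactors = FALSE)
}

#' Genes connected to TF binding sites by called interactions
#'
#' A gene is connected to a peak when a called promoter-distal interaction
#' links its promoter to the restriction fragment containing the peak
#' midpoint. Promoter-promoter calls are excluded by default (as in the
#' figure-3-style analyses); an optional minimum interaction distance
#' reproduces the 15-kb variant.
#'
#' @param tfbs data.frame of binding sites (`chrom`, `start`, `end`).
#' @param calls a `hicap_calls` set.
#' @param fragmap a `hicap_fragmap`.
#' @param min_distance minimum interaction distance in bp (default 0; set
#'   15000 for the long-range variant).
#' @param exclude_pp drop PP calls before matching (default TRUE).
#' @return data.frame `peak`, `frag_id`, `gene_id` (one row per
#'   peak-gene link); the gene set is `unique(out$gene_id)`.
#' @export
connected_genes <- function(tfbs, calls, fragmap, min_distance = 0,
                            exclude_pp = TRUE) {
  mid <- floor((tfbs$start + tfbs$end) / 2)
  frag <- locate_fragment(fragmap, tfbs$chrom, mid)$frag_id
  use <- calls$type == "PD"
  if (!exclude_pp) use <- use | calls$type == "PP"
  if (min_distance > 0)
    use <- use & !is.na(calls$distance) & calls$distance >= min_distance
  cc <- calls[use, , drop = FALSE]
  ## a fragment can partner several promoters; collect all matches
  out <- list()
  for (i in seq_along(frag)) {
    hit <- which(cc$partner == paste0("F", frag[i]))
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(peak = i, frag_id = frag[i],
                                            gene_id = cc$anchor_gene[hit],
                                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(peak = integer(), frag_id = integer(),
                      gene_id = character()))
  unique(do.call(rbind, out))
}

#' Perturbation counts for the fold-improvement test
#'
#' Builds the Nc/Nh/Uc/Uh counts for one TF: Nc unique closest genes to its
#' peaks, Nh unique interaction-connected non-closest genes, Uc and Uh the
#' intersections of each set with the upregulated gene set. Genes both
#' closest and connected are counted in Nc only (the comparison is
#' non-closest connected genes vs all closest genes).
#'
#' @param tfbs data.frame of the TF's binding sites.
#' @param calls a `hicap_calls` set.
#' @param fragmap a `hicap_fragmap`.
#' @param tss_table data.frame with `chrom`, `tss`, `gene_id`.
#' @param upregulated character vector of upregulated gene ids (from
#'   [de_genes()]).
#' @param min_distance optional minimum interaction distance (bp).
#' @return list with `Nc`, `Nh`, `Uc`, `Uh`.
#' @export
perturbation_counts <- function(tfbs, calls, fragmap, tss_table, upregulated,
                                min_distance = 0) {
  closest <- unique(stats::na.omit(closest_genes(tfbs, tss_table)$gene_id))
  conn <- unique(connected_genes(tfbs, calls, fragmap, min_distance)$gene_id)
  noncl <- setdiff(conn, closest)
  list(Nc = length(closest), Nh = length(noncl),
       Uc = length(intersect(closest, upregulated)),
       Uh = length(intersect(noncl, upregulated)))
}

#' Fold improvement of interaction-supported over closest-gene prediction
#'
#' fold = (Uh/Nh) / (Uc/Nc); the chi-squared p-value takes (Uh, Uc) as the
#' observed split of the Uh + Uc upregulated genes and Nh/(Nh+Nc) vs
#' Nc/(Nh+Nc) as the expected proportions (1 df, no continuity correction).
#' Uc = 0 yields an infinite fold, flagged.
#'
#' @param counts list or one-row data.frame with `Nc`, `Nh`, `Uc`, `Uh`.
#' @return list: `fold`, `chi2`, `p`, `undefined` (TRUE when Uc = 0).
#' @export
fold_improvement <- function(counts) {
  Nc <- counts$Nc; Nh <- counts$Nh; Uc <- counts$Uc; Uh <- counts$Uh
  stopifnot(Nc > 0, Nh > 0, Uc + Uh > 0, Uc <= Nc, Uh <= Nh)
  undef <- Uc == 0
  fold <- if (undef) Inf else (Uh / Nh) / (Uc / Nc)
  ts <- chisq_gof(c(Uh, Uc), c(Nh, Nc) / (Nh + Nc))
  list(fold = fold, chi2 = ts$chi2, p = ts$p, undefined = undef)
}

#' Compound fold-improvement test over several TFs
#'
#' Element-wise sums of Nc, Nh, Uc, Uh over all TFs, then the same
#' fold-improvement test.
#'
#' @param per_tf_counts list of per-TF count lists (each with `Nc`, `Nh`,
#'   `Uc`, `Uh`).
#' @return as [fold_improvement()], plus `counts` (the summed counts).
#' @export
compound_test <- function(per_tf_counts) {
  stopifnot(length(per_tf_counts) >= 1L)
  tot <- list(
    Nc = sum(vapply(per_tf_counts, `[[`, numeric(1), "Nc")),
    Nh = sum(vapply(per_tf_counts, `[[`, numeric(1), "Nh")),
    Uc = sum(vapply(per_tf_counts, `[[`, numeric(1), "Uc")),
    Uh = sum(vapply(per_tf_counts, `[[`, numeric(1), "Uh"))
  )
  c(fold_improvement(tot), list(counts = tot))
}

#' Closest genes with vs without interaction support
#'
#' Partitions the closest genes (to TF binding sites) by whether the
#' gene-peak link also has interaction support, and compares upregulation
#' rates between the partitions: fold = upregulated fraction (with support) /
#' upregulated fraction (without support), with a Fisher's exact p on the
#' 2x2 table.
#'
#' @inheritParams perturbation_counts
#' @return list: `fold`, `odds_ratio`, `p`, `n_with`, `n_without`.
#' @export
closest_split_test <- function(tfbs, calls, fragmap, tss_table, upregulated,
                               min_distance = 0) {
  cg <- closest_genes(tfbs, tss_table)
  conn <- connected_genes(tfbs, calls, fragmap, min_distance)
  ## a closest gene is "supported" when one of its peaks links to it
  key_cg <- paste(cg$peak, cg$gene_id)
  key_conn <- paste(conn$peak, conn$gene_id)
  supported_genes <- unique(cg$gene_id[key_cg %in% key_conn])
  all_genes <- unique(stats::na.omit(cg$gene_id))
  unsupported_genes <- setdiff(all_genes, supported_genes)
  if (length(supported_genes) == 0L || length(unsupported_genes) == 0L)
    stop("degenerate partition: no closest genes ",
         if (length(supported_genes) == 0L) "with" else "without",
         " interaction support")
  a <- sum(supported_genes %in% upregulated)
  b <- length(supported_genes) - a
  c_ <- sum(unsupported_genes %in% upregulated)
  d <- length(unsupported_genes) - c_
  ft <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2L))
  rate_w <- a / (a + b); rate_wo <- c_ / (c_ + d)
  list(fold = if (rate_wo > 0) rate_w / rate_wo else Inf,
       odds_ratio = (a * d) / (b * c_),   # sample OR of the 2x2 table
       p = ft$p.value,
       n_with = a + b, n_without = c_ + d)
}
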