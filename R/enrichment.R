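#' Prepare a ChIP-seq feature track for enrichment analysis
#'
#' Keeps the `top_k` highest-scoring intervals (to control for different
#' signal and background levels across experiments) and symmetrically extends
#' intervals shorter than `min_len` to `min_len` bp around their midpoint
#' (clipped at position 0).
#'
#' @param features data.frame with `chrom`, `start`, `end` and, when
#'   `nrow > top_k`, a numeric `score`.
#' @param top_k number of top-scoring intervals to retain (default 5000).
#' @param min_len minimum interval length after extension (default 1000).
#' @return the filtered/extended feature data.frame.
#' @export
prepare_features <- function(features, top_k = 5000L, min_len = 1000L) {
  f <- as.data.frame(features)
  if (nrow(f) > top_k) {
    if (!"score" %in% names(f) || anyNA(f$score))
      stop("scores required to select top ", top_k, " regions")
    f <- f[order(-f$score), , drop = FALSE][seq_len(top_k), , drop = FALSE]
  }
  w <- f$end - f$start
  short <- w < min_len
  if (any(short)) {
    mid <- floor((f$start[short] + f$end[short]) / 2)
    f$start[short] <- pmax(0L, as.integer(mid - floor(min_len / 2)))
    f$end[short] <- f$start[short] + as.integer(min_len)
  }
  rownames(f) <- NULL
  f
}

#' Sample a distance-matched background interval set
#'
#' Draws background regions that mimic the promoter-anchored interaction set:
#' each region is centered at a randomly chosen TSS offset by a distance
#' resampled from the empirical cis interaction-distance distribution, on a
#' random side, with a length resampled from the observed distal-fragment
#' lengths. This preserves the non-random placement of genes when computing
#' expected overlaps.
#'
#' @param calls a `hicap_calls` set with cis PD calls.
#' @param tss_table data.frame with `chrom`, `tss`.
#' @param n_samples number of background regions.
#' @param chrom_lengths named vector of chromosome lengths (for clipping).
#' @param seed optional integer seed (reproducible draws).
#' @return data.frame `chrom`, `start`, `end`, plus bookkeeping columns
#'   `anchor_tss` (the TSS each region was placed around) and
#'   `sampled_distance` (the resampled interaction distance).
#' @export
sample_background <- function(calls, tss_table, n_samples,
                              chrom_lengths, seed = NULL) {
  pd <- calls[calls$type == "PD" & !calls$trans, , drop = FALSE]
  if (nrow(pd) == 0L) stop("no cis promoter-distal calls to match")
  dists <- pd$distance
  lens <- pd$end_b - pd$start_b
  with_seed_if(seed, {
    ti <- sample.int(nrow(tss_table), n_samples, replace = TRUE)
    d <- resample(dists, n_samples)
    side <- sample(c(-1, 1), n_samples, replace = TRUE)
    L <- resample(lens, n_samples)
    center <- tss_table$tss[ti] + side * d
    chrom <- tss_table$chrom[ti]
    start <- as.integer(round(center - L / 2))
    end <- start + as.integer(L)
    ## clip to chromosome bounds
    cl <- as.integer(chrom_lengths[chrom])
    shift <- pmax(0L, -start) - pmax(0L, end - cl)
    start <- pmax(0L, start + shift)
    end <- pmin(cl, end + shift)
    data.frame(chrom = chrom, start = start, end = pmax(end, start + 1L),
               anchor_tss = tss_table$tss[ti], sampled_distance = d)
  })
}

#' Observed/expected overlap signal against a background set
#'
#' The observed fraction is the share of query regions overlapping (by at
#' least one nucleotide) any feature interval; the expected fraction is the
#' same share among background regions. Signal = observed/expected, with a
#' 1-df chi-squared goodness-of-fit p-value of the observed overlap count
#' against the expected fraction.
#'
#' @param regions query intervals (`chrom`, `start`, `end`), e.g. distal
#'   regions of called interactions.
#' @param features a prepared feature track.
#' @param background background intervals (e.g. from [sample_background()]).
#' @return list: `observed_fraction`, `expected_fraction`, `signal` (`NA`
#'   when the expected fraction is 0), `chi2`, `p`.
#' @export
overlap_signal <- function(regions, features, background) {
  stopifnot(nrow(regions) > 0L, nrow(background) > 0L)
  obs_hit <- interval_overlap_any(regions, features)
  exp_frac <- mean(interval_overlap_any(background, features))
  obs_frac <- mean(obs_hit)
  if (exp_frac == 0)
    return(list(observed_fraction = obs_frac, expected_fraction = 0,
                signal = NA_real_, chi2 = NA_real_, p = NA_real_))
  if (exp_frac == 1 || obs_frac == exp_frac) {
    ## degenerate GOF (zero expected in one cell, or exact agreement)
    ts <- if (obs_frac == exp_frac) list(chi2 = 0, p = 1)
          else list(chi2 = NA_real_, p = NA_real_)
  } else {
    ts <- chisq_gof(c(sum(obs_hit), sum(!obs_hit)),
                    c(exp_frac, 1 - exp_frac))
  }
  list(observed_fraction = obs_frac, expected_fraction = exp_frac,
       signal = obs_frac / exp_frac, chi2 = ts$chi2, p = ts$p)
}

#' TAD containment of interactions by distance bin
#'
#' Classifies every cis interaction as completely contained within one TAD,
#' spanning two or more TADs, or with one or both anchor midpoints outside
#' annotated TADs, per interaction-distance bin. Controls are generated by
#' re-placing interactions at random genomic positions (random chromosome,
#' random start) while keeping the distance the same. Per bin and class, a
#' 1-df chi-squared test compares observed and control counts; the highest p
#' per class across bins is reported as `max_p`.
#'
#' @param calls a `hicap_calls` set (cis calls are used).
#' @param tads data.frame of TADs (`chrom`, `start`, `end`), non-overlapping
#'   per chromosome.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param bins numeric breakpoints on distance; default log2 bins
#'   1000, 2000, 4000, ..., 128000, Inf.
#' @param n_control number of randomized control interactions (default
#'   10 * number of cis calls).
#' @param seed optional integer seed.
#' @return list: `table` (per-bin observed/control fractions and per-class
#'   chi-squared p), `max_p` (named by class).
#' @export
tad_containment <- function(calls, tads, chrom_lengths,
                            bins = c(2^(0:7) * 1000, Inf),
                            n_control = NULL, seed = NULL) {
  cis <- calls[!calls$trans & !is.na(calls$distance), , drop = FALSE]
  if (nrow(cis) == 0L) stop("no same-chromosome calls")
  if (is.null(n_control)) n_control <- 10L * nrow(cis)

  classify <- function(chrom, x1, x2) {
    t1 <- point_overlaps(chrom, as.integer(pmin(x1, x2)), tads)
    t2 <- point_overlaps(chrom, as.integer(pmax(x1, x2)), tads)
    i1 <- vapply(t1, function(z) if (is.null(z)) NA_integer_ else z[1L],
                 integer(1))
    i2 <- vapply(t2, function(z) if (is.null(z)) NA_integer_ else z[1L],
                 integer(1))
    out <- rep("outside", length(i1))
    both <- !is.na(i1) & !is.na(i2)
    out[both & i1 == i2] <- "within"
    out[both & i1 != i2] <- "spanning"
    out
  }
  mid_a <- (cis$start_a + cis$end_a) / 2
  mid_b <- (cis$start_b + cis$end_b) / 2
  obs_class <- classify(cis$chrom_a, mid_a, mid_b)
  obs_dist <- cis$distance

  ctrl <- with_seed_if(seed, {
    d <- resample(obs_dist, n_control)
    cc <- sample(names(chrom_lengths), n_control, replace = TRUE,
                 prob = chrom_lengths / sum(chrom_lengths))
    maxstart <- pmax(1, chrom_lengths[cc] - d - 1)
    x1 <- floor(runif(n_control, 0, maxstart))
    list(chrom = cc, x1 = x1, x2 = pmin(x1 + d, chrom_lengths[cc] - 1),
         dist = d)
  })
  ctrl_class <- classify(ctrl$chrom, ctrl$x1, ctrl$x2)

  bin_of <- function(d) cut(d, breaks = c(0, bins), right = FALSE)
  obs_bin <- bin_of(obs_dist); ctrl_bin <- bin_of(ctrl$dist)
  classes <- c("within", "spanning", "outside")
  rows <- list()
  for (b in levels(obs_bin)) {
    oi <- obs_bin == b; ci <- ctrl_bin == b
    no <- sum(oi); nc <- sum(ci)
    if (no == 0L) next
    rec <- list(bin = b, n_obs = no, n_ctrl = nc)
    for (cl in classes) {
      fo <- mean(obs_class[oi] == cl)
      fc <- if (nc > 0L) mean(ctrl_class[ci] == cl) else NA_real_
      p <- if (nc > 0L && fc > 0 && fc < 1)
        chisq_gof(c(sum(obs_class[oi] == cl), sum(obs_class[oi] != cl)),
                  c(fc, 1 - fc))$p
      else if (!is.na(fc) && fo == fc) 1 else NA_real_
      rec[[paste0("obs_", cl)]] <- fo
      rec[[paste0("ctrl_", cl)]] <- fc
      rec[[paste0("p_", cl)]] <- p
    }
    rows[[b]] <- as.data.frame(rec)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  max_p <- vapply(classes, function(cl)
    suppressWarnings(max(tab[[paste0("p_", cl)]], na.rm = TRUE)), numeric(1))
  list(table = tab, max_p = max_p)
}

#' RPKM of genomic regions from read positions
#'
#' RPKM = reads in region x 1e9 / (region length in bp x total mapped
#' reads). Reads are counted by their (0-based) position.
#'
#' @param regions data.frame `chrom`, `start`, `end` (all lengths > 0).
#' @param reads data.frame of read positions (`chrom`, `pos`).
#' @param total_mapped_reads library size used for normalization (> 0).
#' @return numeric RPKM vector, one per region.
#' @export
region_rpkm <- function(regions, reads, total_mapped_reads) {
  stopifnot(total_mapped_reads > 0)
  len <- regions$end - regions$start
  if (any(len <= 0)) stop("zero-length region")
  counts <- integer(nrow(regions))
  hits <- point_overlaps(reads$chrom, reads$pos, regions)
  tab <- table(unlist(hits))
  counts[as.integer(names(tab))] <- as.integer(tab)
  counts * 1e9 / (len * total_mapped_reads)
}

#' Enhancer-RNA expression of intergenic distal regions
#'
#' Restricts called distal regions to those not overlapping any annotated
#' gene (intergenic), generates matched random regions (same empirical
#' distance-from-promoter distribution and resampled lengths, also
#' non-genic), quantifies both sets as RPKM from nascent-transcription read
#' positions, and per threshold runs a 1-df chi-squared test on the fraction
#' of regions expressed above the threshold.
#'
#' @param calls a `hicap_calls` set with cis PD calls.
#' @param gene_annotation data.frame of gene bodies (`chrom`, `start`,
#'   `end`).
#' @param gro_reads data.frame of read positions (`chrom`, `pos`).
#' @param tss_table data.frame with `chrom`, `tss` (for matched sampling).
#' @param chrom_lengths named chromosome lengths.
#' @param total_mapped_reads library size; default `nrow(gro_reads)`.
#' @param thresholds RPKM exceedance thresholds (default 0.1 and 1.0).
#' @param seed optional integer seed.
#' @return list: `table` (per threshold: fractions above threshold in
#'   observed and random sets, chi2, p), `observed_rpkm`, `random_rpkm`,
#'   `intergenic_fraction`.
#' @export
erna_analysis <- function(calls, gene_annotation, gro_reads, tss_table,
                          chrom_lengths, total_mapped_reads = nrow(gro_reads),
                          thresholds = c(0.1, 1.0), seed = NULL) {
  pd <- calls[calls$type == "PD" & !calls$trans, , drop = FALSE]
  distal <- unique(data.frame(chrom = pd$chrom_b, start = pd$start_b,
                              end = pd$end_b))
  genic <- interval_overlap_any(distal, gene_annotation)
  inter <- distal[!genic, , drop = FALSE]
  if (nrow(inter) == 0L) stop("no intergenic distal regions")

  ## matched random regions: rejection-sample non-genic, distance-matched
  rand <- with_seed_if(seed, {
    acc <- list(); have <- 0L; tries <- 0L
    while (have < nrow(inter) && tries < 50L) {
      cand <- sample_background(calls, tss_table, 2L * nrow(inter),
                                chrom_lengths, seed = NULL)
      cand <- cand[!interval_overlap_any(cand, gene_annotation), ,
                   drop = FALSE]
      acc[[length(acc) + 1L]] <- cand
      have <- have + nrow(cand); tries <- tries + 1L
    }
    out <- do.call(rbind, acc)
    if (nrow(out) < nrow(inter))
      stop("could not sample enough non-genic matched regions")
    out[seq_len(nrow(inter)), , drop = FALSE]
  })

  obs_rpkm <- region_rpkm(inter, gro_reads, total_mapped_reads)
  rnd_rpkm <- region_rpkm(rand, gro_reads, total_mapped_reads)
  rows <- lapply(thresholds, function(th) {
    fo <- mean(obs_rpkm > th); fr <- mean(rnd_rpkm > th)
    ts <- if (fr > 0 && fr < 1)
      chisq_gof(c(sum(obs_rpkm > th), sum(obs_rpkm <= th)), c(fr, 1 - fr))
    else if (fo == fr) list(chi2 = 0, p = 1)
    else list(chi2 = NA_real_, p = NA_real_)
    data.frame(threshold = th, frac_observed = fo, frac_random = fr,
               chi2 = ts$chi2, p = ts$p)
  })
  list(table = do.call(rbind, rows),
       observed_rpkm = obs_rpkm, random_rpkm = rnd_rpkm,
       intergenic_fraction = nrow(inter) / nrow(distal))
}

#' Correlation of distal-region and target-gene expression
#'
#' Spearman correlation between distal-region expression and the expression
#' of the connected gene; when several distal regions connect to one gene
#' their RPKMs are summed. Significance by label permutation: the gene
#' expression vector is permuted `n_perm` times and the p-value is the
#' fraction of permutations with rho at least as large as observed, floored
#' at `1/n_perm`.
#'
#' @param distal_rpkm named numeric vector (names = distal region ids).
#' @param gene_rpkm named numeric vector (names = gene ids).
#' @param pairing data.frame with columns `distal_id`, `gene_id`.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed.
#' @return list: `rho`, `perm_p`, `n` (number of gene-level pairs).
#' @export
expression_correlation <- function(distal_rpkm, gene_rpkm, pairing,
                                   n_perm = 1000L, seed = NULL) {
  x <- tapply(distal_rpkm[pairing$distal_id], pairing$gene_id, sum)
  y <- gene_rpkm[names(x)]
  ok <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant expression vector; rho undefined")
  rho <- stats::cor(x, y, method = "spearman")
  hits <- with_seed_if(seed, {
    sum(vapply(seq_len(n_perm), function(i)
      stats::cor(x, sample(y), method = "spearman") >= rho, logical(1)))
  })
  list(rho = rho, perm_p = max(hits / n_perm, 1 / n_perm), n = length(x))
}
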