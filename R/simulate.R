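#' Simulation configuration
#'
#' Assembles the parameter set for the synthetic capture Hi-C world. The
#' defaults describe a desk-scale experiment: a 10-Mb uniform-composition
#' genome in two chromosomes (about one GATC per 256 bp), 400 promoters, 300
#' planted promoter-distal loops at log-normal distances (median 30 kb) with
#' 8 expected read pairs per replicate each, and 2 x 10^5 read pairs per
#' replicate in two biological replicates. Background ligation pairs follow
#' a distance-decay contact probability proportional to distance^-alpha over
#' 1 kb - 2 Mb; a configured share of pairs are self-ligation products
#' (< 1 kb apart or same-fragment) and exact PCR duplicates are injected on
#' top.
#'
#' @param genome_length total genome size in bp (default 1e7).
#' @param n_chrom number of chromosomes (default 2).
#' @param gc GC content of the random genome (default 0.5).
#' @param n_promoters number of promoters/genes (default 400).
#' @param n_planted_loops planted promoter-distal loops (default 300).
#' @param n_planted_pp,n_planted_ee planted promoter-promoter and
#'   distal-distal contacts (default 40 each).
#' @param loop_meanlog,loop_sdlog log-normal parameters of planted loop
#'   distances (default log(3e4), 0.8).
#' @param loop_pairs_mean expected read pairs per planted contact per
#'   replicate (default 8).
#' @param pairs_per_replicate sequencing depth in read pairs per replicate
#'   (default 2e5).
#' @param n_replicates biological replicates (default 2).
#' @param bg_on_target_frac share of depth that is informative on-target
#'   background (one end on a probe target, distance-decay partner;
#'   default 0.05).
#' @param close_pair_frac share of depth that is self-ligation-like
#'   (< 1 kb / same fragment; default 0.15).
#' @param duplicate_rate share of depth injected as exact duplicates
#'   (default 0.10).
#' @param decay_alpha,decay_min,decay_max distance-decay exponent and range
#'   (default 1.0 over 1 kb - 2 Mb).
#' @param enhancer_mark_frac fraction of planted distal regions carrying a
#'   simulated enhancer mark (default 0.8).
#' @param n_decoy_marks unrelated enhancer-mark intervals (default 300).
#' @param tad_mean_size mean TAD size in bp (default 5e5).
#' @param n_tfs simulated transcription factors (default 5).
#' @param tf_frac_bound fraction of planted distal regions bound per TF
#'   (default 0.3).
#' @param tf_effect fold increase in upregulation probability for genes
#'   connected to a TF-bound distal region (1 = null; default 4).
#' @param base_up_rate baseline per-gene upregulation probability after a
#'   TF perturbation (default 0.05).
#' @param erna_correlation log-scale correlation between planted eRNA level
#'   and target-gene expression (0 = null; default 0.7).
#' @param gro_depth nascent-transcription reads emitted (default 5e4).
#' @return a `sim_config` list.
#' @export
sim_config <- function(genome_length = 1e7, n_chrom = 2L, gc = 0.5,
                       n_promoters = 400L, n_planted_loops = 300L,
                       n_planted_pp = 40L, n_planted_ee = 40L,
                       loop_meanlog = log(3e4), loop_sdlog = 0.8,
                       loop_pairs_mean = 8,
                       pairs_per_replicate = 2e5, n_replicates = 2L,
                       bg_on_target_frac = 0.05, close_pair_frac = 0.15,
                       duplicate_rate = 0.10,
                       decay_alpha = 1.0, decay_min = 1000, decay_max = 2e6,
                       enhancer_mark_frac = 0.8, n_decoy_marks = 300L,
                       tad_mean_size = 5e5,
                       n_tfs = 5L, tf_frac_bound = 0.3, tf_effect = 4,
                       base_up_rate = 0.05,
                       erna_correlation = 0.7, gro_depth = 5e4) {
  cfg <- as.list(environment())
  stopifnot(cfg$gc >= 0, cfg$gc <= 1, cfg$duplicate_rate >= 0,
            cfg$duplicate_rate <= 1, cfg$bg_on_target_frac >= 0,
            cfg$close_pair_frac >= 0, cfg$pairs_per_replicate >= 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a genome with promoter and gene annotation
#'
#' Generates `n_chrom` random chromosomes at the configured GC content
#' (i.i.d. bases, so a 4-bp site occurs about once per 256 bp at GC 0.5),
#' places promoters at regular spacing with jitter while keeping a margin at
#' chromosome ends, and annotates a gene body downstream of each TSS.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed (mandatory for reproducibility).
#' @return list: `genome` (named character vector), `tss_table` (`chrom`,
#'   `tss`, `strand`, `promoter_id`, `gene_id`), `gene_annotation` (`chrom`,
#'   `start`, `end`, `gene_id`, `strand`), `chrom_lengths`.
#' @export
simulate_genome <- function(cfg, seed) {
  withr::with_seed(seed, {
    clen <- rep(floor(cfg$genome_length / cfg$n_chrom), cfg$n_chrom)
    names(clen) <- paste0("chr", seq_len(cfg$n_chrom))
    pbase <- c(A = (1 - cfg$gc) / 2, C = cfg$gc / 2,
               G = cfg$gc / 2, T = (1 - cfg$gc) / 2)
    genome <- vapply(clen, function(L)
      paste(sample(names(pbase), L, replace = TRUE, prob = pbase),
            collapse = ""), character(1))

    margin <- min(2.5e6, floor(min(clen) / 4))
    usable <- clen - 2 * margin
    n_per <- round(cfg$n_promoters * clen / sum(clen))
    n_per[cfg$n_chrom] <- cfg$n_promoters - sum(n_per[-cfg$n_chrom])
    if (cfg$n_promoters > 0 && any(usable / pmax(n_per, 1L) < 2000))
      stop("promoters unplaceable at requested density")
    tss <- NULL
    if (cfg$n_promoters > 0) {
      rows <- lapply(seq_len(cfg$n_chrom), function(i) {
        if (n_per[i] == 0L) return(NULL)
        spacing <- usable[i] / n_per[i]
        pos <- as.integer(margin + spacing * (seq_len(n_per[i]) - 0.5) +
                            round(stats::runif(n_per[i], -0.2, 0.2) * spacing))
        data.frame(chrom = names(clen)[i], tss = pos,
                   strand = sample(c("+", "-"), n_per[i], replace = TRUE),
                   stringsAsFactors = FALSE)
      })
      tss <- do.call(rbind, rows)
      tss$promoter_id <- sprintf("P%04d", seq_len(nrow(tss)))
      tss$gene_id <- sprintf("G%04d", seq_len(nrow(tss)))
    } else {
      tss <- data.frame(chrom = character(), tss = integer(),
                        strand = character(), promoter_id = character(),
                        gene_id = character())
    }
    glen <- if (nrow(tss)) as.integer(2000 + stats::rlnorm(nrow(tss),
                                                           log(8000), 0.6))
            else integer()
    gene <- data.frame(
      chrom = tss$chrom,
      start = ifelse(tss$strand == "+", tss$tss,
                     pmax(0L, tss$tss - glen)),
      end = ifelse(tss$strand == "+",
                   pmin(clen[tss$chrom], tss$tss + glen), tss$tss),
      gene_id = tss$gene_id, strand = tss$strand,
      stringsAsFactors = FALSE
    )
    list(genome = genome, tss_table = tss, gene_annotation = gene,
         chrom_lengths = clen)
  })
}

## inverse-CDF sampler for the distance-decay density d^-alpha on
## [dmin, dmax]; dmax may be a vector (per-draw truncation, used to keep
## partners on the chromosome without piling mass at the ends)
sample_decay <- function(n, alpha, dmin, dmax) {
  u <- stats::runif(n)
  dmax <- pmax(rep_len(dmax, n), dmin + 1)
  if (abs(alpha - 1) < 1e-9) {
    dmin * (dmax / dmin)^u
  } else {
    a1 <- 1 - alpha
    (u * (dmax^a1 - dmin^a1) + dmin^a1)^(1 / a1)
  }
}

## choose planted contacts; distal fragments are never probe-target
## fragments and (promoter, fragment) keys are unique
plant_truth <- function(cfg, fragmap, probes, tss_table, chrom_lengths) {
  target_frags <- unique(locate_fragment(
    fragmap, probes$chrom,
    pmin(probes$start, attr(fragmap, "chrom_lengths")[probes$chrom] - 1L)
  )$frag_id)
  ## (targets never touch chromosome end in practice; use region starts)
  pick_distal <- function(n, anchor_chrom, anchor_pos) {
    out_frag <- integer(n); out_ok <- logical(n)
    d <- as.integer(stats::rlnorm(n, cfg$loop_meanlog, cfg$loop_sdlog))
    d <- pmax(d, 2000L)
    side <- sample(c(-1L, 1L), n, replace = TRUE)
    pos <- anchor_pos + side * d
    L <- chrom_lengths[anchor_chrom]
    pos <- pmin(pmax(pos, 0L), L - 1L)
    fr <- locate_fragment(fragmap, anchor_chrom, pos)$frag_id
    ok <- !(fr %in% target_frags)
    list(frag = fr, ok = ok)
  }
  loops <- NULL; tries <- 0L
  need <- cfg$n_planted_loops
  acc <- list()
  while (need > 0L && tries < 20L) {
    pi <- sample.int(nrow(tss_table), need, replace = TRUE)
    cand <- pick_distal(need, tss_table$chrom[pi], tss_table$tss[pi])
    df <- data.frame(promoter_id = tss_table$promoter_id[pi],
                     gene_id = tss_table$gene_id[pi],
                     chrom = tss_table$chrom[pi],
                     frag_id = cand$frag, stringsAsFactors = FALSE)
    df <- df[cand$ok, , drop = FALSE]
    acc[[length(acc) + 1L]] <- df
    all <- unique(do.call(rbind, acc))
    need <- cfg$n_planted_loops - nrow(all)
    tries <- tries + 1L
  }
  loops <- utils::head(unique(do.call(rbind, acc)), cfg$n_planted_loops)

  pp <- NULL
  if (cfg$n_planted_pp > 0L && nrow(tss_table) >= 2L) {
    a <- sample(tss_table$promoter_id, cfg$n_planted_pp, replace = TRUE)
    b <- sample(tss_table$promoter_id, cfg$n_planted_pp, replace = TRUE)
    keep <- a != b
    pp <- unique(data.frame(p1 = pmin(a, b)[keep], p2 = pmax(a, b)[keep],
                            stringsAsFactors = FALSE))
  }
  ee <- NULL
  dfr <- unique(loops$frag_id)
  if (cfg$n_planted_ee > 0L && length(dfr) >= 2L) {
    a <- resample(dfr, cfg$n_planted_ee)
    b <- resample(dfr, cfg$n_planted_ee)
    keep <- a != b
    ee <- unique(data.frame(f1 = pmin(a, b)[keep], f2 = pmax(a, b)[keep]))
  }
  list(loops = loops, pp = pp, ee = ee)
}

#' Simulate capture Hi-C read ends with planted ground truth
#'
#' Emits per-replicate tables of independently mapped read ends: planted
#' promoter-distal loops (and promoter-promoter / distal-distal contacts)
#' receive Poisson-distributed boosted pair counts; informative background
#' pairs anchor one end on a random probe target with the partner placed at
#' a distance drawn from the decay distribution; off-target background pairs
#' land uniformly; self-ligation-like products (< 1 kb apart or within one
#' fragment) and exact PCR duplicates are injected at the configured rates.
#'
#' @param cfg a [sim_config()].
#' @param sim output of [simulate_genome()].
#' @param fragmap a `hicap_fragmap` of the simulated genome.
#' @param probes a `hicap_probes` set for the simulated TSSs.
#' @param seed integer seed.
#' @return list: `ends` (data.frame `read_id`, `chrom`, `pos`, `strand`,
#'   `replicate` covering all replicates), `truth` (planted `loops`, `pp`,
#'   `ee` tables).
#' @export
simulate_reads <- function(cfg, sim, fragmap, probes, seed) {
  clen <- sim$chrom_lengths
  withr::with_seed(seed, {
    truth <- plant_truth(cfg, fragmap, probes, sim$tss_table, clen)
    px <- expand_probes(probes)
    px_by_prom <- split(seq_len(nrow(px)), px$promoter_id)

    rand_in_targets <- function(prom) {
      ## uniform position within one of the promoter's target regions
      rows <- unlist(lapply(prom, function(p) {
        cand <- px_by_prom[[p]]
        cand[sample.int(length(cand), 1L)]
      }))
      list(chrom = px$chrom[rows],
           pos = px$start[rows] +
             floor(stats::runif(length(rows)) * (px$end[rows] - px$start[rows])))
    }
    rand_in_frag <- function(fid) {
      fi <- match(fid, fragmap$frag_id)
      list(chrom = fragmap$chrom[fi],
           pos = fragmap$start[fi] +
             floor(stats::runif(length(fi)) *
                     (fragmap$end[fi] - fragmap$start[fi])))
    }
    rand_genome <- function(n) {
      cc <- sample(names(clen), n, replace = TRUE, prob = clen / sum(clen))
      list(chrom = cc, pos = floor(stats::runif(n) * clen[cc]))
    }
    strands <- function(n) sample(c("+", "-"), n, replace = TRUE)

    all_reps <- vector("list", cfg$n_replicates)
    for (r in seq_len(cfg$n_replicates)) {
      e1 <- list(); e2 <- list()
      if (cfg$pairs_per_replicate == 0) {   # zero depth: no reads at all
        all_reps[[r]] <- data.frame(read_id = character(),
                                    chrom = character(), pos = integer(),
                                    strand = character(),
                                    replicate = character())
        next
      }
      ## planted PD loops
      k <- stats::rpois(nrow(truth$loops), cfg$loop_pairs_mean)
      idx <- rep(seq_len(nrow(truth$loops)), k)
      if (length(idx)) {
        e1$loop <- rand_in_targets(truth$loops$promoter_id[idx])
        e2$loop <- rand_in_frag(truth$loops$frag_id[idx])
      }
      ## planted PP contacts
      if (!is.null(truth$pp) && nrow(truth$pp)) {
        k <- stats::rpois(nrow(truth$pp), cfg$loop_pairs_mean)
        idx <- rep(seq_len(nrow(truth$pp)), k)
        if (length(idx)) {
          e1$pp <- rand_in_targets(truth$pp$p1[idx])
          e2$pp <- rand_in_targets(truth$pp$p2[idx])
        }
      }
      ## planted EE contacts
      if (!is.null(truth$ee) && nrow(truth$ee)) {
        k <- stats::rpois(nrow(truth$ee), cfg$loop_pairs_mean)
        idx <- rep(seq_len(nrow(truth$ee)), k)
        if (length(idx)) {
          e1$ee <- rand_in_frag(truth$ee$f1[idx])
          e2$ee <- rand_in_frag(truth$ee$f2[idx])
        }
      }
      ## informative on-target background with distance decay
      n_bg <- round(cfg$bg_on_target_frac * cfg$pairs_per_replicate)
      if (n_bg > 0) {
        prom <- sample(sim$tss_table$promoter_id, n_bg, replace = TRUE)
        a <- rand_in_targets(prom)
        L <- clen[a$chrom]
        ## truncate the decay law to the span available on the chromosome
        span <- pmax(a$pos, L - 1 - a$pos)
        d <- round(sample_decay(n_bg, cfg$decay_alpha, cfg$decay_min,
                                pmin(cfg$decay_max, span)))
        fits_left <- d <= a$pos
        fits_right <- d <= L - 1 - a$pos
        side <- ifelse(fits_left & fits_right,
                       sample(c(-1, 1), n_bg, replace = TRUE),
                       ifelse(fits_left, -1, 1))
        pos2 <- pmin(pmax(a$pos + side * d, 0), L - 1)
        e1$bg <- a
        e2$bg <- list(chrom = a$chrom, pos = pos2)
      }
      ## self-ligation-like close pairs
      n_close <- round(cfg$close_pair_frac * cfg$pairs_per_replicate)
      if (n_close > 0) {
        a <- rand_genome(n_close)
        off <- floor(stats::runif(n_close) * 999)
        pos2 <- pmin(pmax(a$pos + off, 0), clen[a$chrom] - 1)
        e1$close <- a
        e2$close <- list(chrom = a$chrom, pos = pos2)
      }
      ## off-target random pairs fill the remaining depth
      n_sofar <- length(e1$loop$pos) + length(e1$pp$pos) +
        length(e1$ee$pos) + n_bg + n_close
      n_dup <- round(cfg$duplicate_rate * cfg$pairs_per_replicate)
      n_off <- max(0L, cfg$pairs_per_replicate - n_sofar - n_dup)
      if (n_off > 0) {
        e1$off <- rand_genome(n_off)
        e2$off <- rand_genome(n_off)
      }
      p1 <- data.frame(chrom = unlist(lapply(e1, `[[`, "chrom")),
                       pos = as.integer(unlist(lapply(e1, `[[`, "pos"))))
      p2 <- data.frame(chrom = unlist(lapply(e2, `[[`, "chrom")),
                       pos = as.integer(unlist(lapply(e2, `[[`, "pos"))))
      n <- nrow(p1)
      s1 <- strands(n); s2 <- strands(n)
      ## exact duplicates of randomly chosen pairs
      if (n_dup > 0 && n > 0) {
        di <- sample.int(n, n_dup, replace = TRUE)
        p1 <- rbind(p1, p1[di, ]); p2 <- rbind(p2, p2[di, ])
        s1 <- c(s1, s1[di]); s2 <- c(s2, s2[di])
        n <- n + n_dup
      }
      rid <- sprintf("r%d_%07d", r, seq_len(n))
      all_reps[[r]] <- data.frame(
        read_id = c(rid, rid),
        chrom = c(p1$chrom, p2$chrom),
        pos = c(p1$pos, p2$pos),
        strand = c(s1, s2),
        replicate = paste0("rep", r),
        stringsAsFactors = FALSE
      )
    }
    list(ends = do.call(rbind, all_reps), truth = truth)
  })
}

#' Simulate downstream omics tracks and tables
#'
#' Generates the inputs of the enrichment, perturbation and network
#' analyses, consistent with the planted ground truth: enhancer-mark
#' intervals on a configured fraction of planted distal regions (plus scored
#' decoys), TADs tiling each chromosome, nascent-transcription (GRO-seq
#' style) read positions whose signal at planted distal regions correlates
#' with target-gene expression on the log scale at the configured
#' correlation, a gene expression table, per-TF binding-site tracks at
#' planted distal regions, per-TF differential-expression tables in which
#' connected genes are upregulated `tf_effect`-fold more often than
#' baseline, and a GO annotation table.
#'
#' @param cfg a [sim_config()].
#' @param sim output of [simulate_genome()].
#' @param truth planted truth from [simulate_reads()].
#' @param fragmap a `hicap_fragmap`.
#' @param seed integer seed.
#' @return list: `enhancer_marks`, `tads`, `gro_reads`, `expression`
#'   (`gene_id`, `rpkm`), `tfbs` (named list of data.frames), `de_tables`
#'   (named list), `go_table`, `truth_up` (named list of truly
#'   effect-carrying gene sets), `distal_regions` (planted, with `frag_id`,
#'   coords, `gene_id`, `erna_level`).
#' @export
simulate_omics <- function(cfg, sim, truth, fragmap, seed) {
  clen <- sim$chrom_lengths
  withr::with_seed(seed, {
    fl <- truth$loops
    fi <- match(fl$frag_id, fragmap$frag_id)
    distal <- data.frame(frag_id = fl$frag_id, chrom = fragmap$chrom[fi],
                         start = fragmap$start[fi], end = fragmap$end[fi],
                         gene_id = fl$gene_id, stringsAsFactors = FALSE)
    distal <- distal[!duplicated(distal$frag_id), , drop = FALSE]

    ## gene expression (log-normal, with a silent tail)
    rpkm <- stats::rlnorm(nrow(sim$tss_table), log(5), 1.2)
    rpkm[stats::runif(length(rpkm)) < 0.2] <- 0
    expression <- data.frame(gene_id = sim$tss_table$gene_id, rpkm = rpkm)

    ## eRNA level: correlated with target-gene expression on log scale
    g_log <- log1p(expression$rpkm[match(distal$gene_id,
                                         expression$gene_id)])
    g_z <- as.numeric(scale(g_log))
    rho <- cfg$erna_correlation
    e_z <- rho * g_z + sqrt(max(0, 1 - rho^2)) * stats::rnorm(nrow(distal))
    distal$erna_level <- exp(0.8 * e_z)          # relative transcription rate

    ## enhancer marks: fraction of planted distal regions + decoys
    marked <- distal[stats::runif(nrow(distal)) < cfg$enhancer_mark_frac, ]
    decoy_c <- sample(names(clen), cfg$n_decoy_marks, replace = TRUE,
                      prob = clen / sum(clen))
    decoy_s <- floor(stats::runif(cfg$n_decoy_marks) * (clen[decoy_c] - 600))
    marks <- rbind(
      data.frame(chrom = marked$chrom, start = marked$start,
                 end = marked$end, stringsAsFactors = FALSE),
      data.frame(chrom = decoy_c, start = as.integer(decoy_s),
                 end = as.integer(decoy_s + 500), stringsAsFactors = FALSE))
    marks$score <- stats::runif(nrow(marks), 1, 10)

    ## TADs: tile each chromosome with log-normal sizes, small gaps
    tad_rows <- lapply(names(clen), function(cc) {
      pos <- 0; out <- list()
      while (pos < clen[[cc]] - 1e4) {
        w <- min(round(stats::rlnorm(1, log(cfg$tad_mean_size), 0.4)),
                 clen[[cc]] - pos)
        out[[length(out) + 1L]] <- data.frame(chrom = cc, start = pos,
                                              end = pos + w)
        gap <- if (stats::runif(1) < 0.3) round(stats::runif(1, 5e3, 3e4))
               else 0
        pos <- pos + w + gap
      }
      do.call(rbind, out)
    })
    tads <- do.call(rbind, tad_rows)
    tads$end <- pmin(tads$end, clen[tads$chrom])

    ## GRO-seq-like reads: planted eRNA signal + uniform background
    sig_frac <- 0.5
    n_sig <- round(sig_frac * cfg$gro_depth)
    wts <- distal$erna_level * (distal$end - distal$start)
    di <- sample.int(nrow(distal), n_sig, replace = TRUE,
                     prob = wts / sum(wts))
    sig_pos <- distal$start[di] +
      floor(stats::runif(n_sig) * (distal$end[di] - distal$start[di]))
    n_bg <- cfg$gro_depth - n_sig
    bg_c <- sample(names(clen), n_bg, replace = TRUE,
                   prob = clen / sum(clen))
    gro <- data.frame(
      chrom = c(distal$chrom[di], bg_c),
      pos = as.integer(c(sig_pos, floor(stats::runif(n_bg) * clen[bg_c]))),
      stringsAsFactors = FALSE)

    ## TF binding sites at planted distal regions + DE tables
    tfbs <- list(); de_tables <- list(); truth_up <- list()
    genes <- sim$tss_table$gene_id
    for (f in seq_len(cfg$n_tfs)) {
      tf <- sprintf("TF%02d", f)
      bi <- which(stats::runif(nrow(distal)) < cfg$tf_frac_bound)
      mid <- floor((distal$start[bi] + distal$end[bi]) / 2)
      tfbs[[tf]] <- data.frame(
        chrom = distal$chrom[bi],
        start = pmax(0L, as.integer(mid - 100L)),
        end = as.integer(mid + 100L),
        score = stats::runif(length(bi), 1, 100), stringsAsFactors = FALSE)
      connected <- unique(distal$gene_id[bi])
      p_up <- ifelse(genes %in% connected,
                     pmin(cfg$base_up_rate * cfg$tf_effect, 0.9),
                     cfg$base_up_rate)
      up <- stats::runif(length(genes)) < p_up
      de_tables[[tf]] <- data.frame(
        gene_id = genes,
        fold_change = ifelse(up, 1.5 + stats::rexp(length(genes), 1),
                             stats::runif(length(genes), 0.6, 1.5)),
        fdr = ifelse(up, stats::runif(length(genes), 0, 0.05),
                     stats::runif(length(genes), 0.05, 1)),
        stringsAsFactors = FALSE)
      truth_up[[tf]] <- genes[up]
    }

    ## GO table: random terms; genes of planted loops sharing a distal
    ## region are co-annotated, giving the pair-sharing test real signal
    n_terms <- 40L
    go <- list()
    for (t in seq_len(n_terms)) {
      term <- sprintf("GO:%04d", t)
      members <- sample(genes, max(3L, stats::rpois(1, 12)))
      go[[t]] <- data.frame(gene_id = members, term = term,
                            stringsAsFactors = FALSE)
    }
    go_table <- unique(do.call(rbind, go))

    list(enhancer_marks = marks, tads = tads, gro_reads = gro,
         expression = expression, tfbs = tfbs, de_tables = de_tables,
         go_table = go_table, truth_up = truth_up, distal_regions = distal)
  })
}
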