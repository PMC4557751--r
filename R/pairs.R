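#' Pair independently mapped read ends
#'
#' Capture Hi-C read ends are mapped independently; this reassembles them
#' into read pairs by `read_id`. Ends within a pair are ordered canonically
#' by (chrom, pos, strand) so pair identity is orientation-free. Read ids
#' with a single mapped end are dropped and counted (attribute
#' `n_singletons`); more than two ends per read id is an error.
#'
#' @param ends data.frame with columns `read_id`, `chrom`, `pos` (0-based
#'   leftmost mapped base), `strand` (`"+"`/`"-"`), and optionally
#'   `replicate` (a label; both ends of a read must share it).
#' @return a `hicap_pairs` data.frame with columns `read_id`, `chrom1`,
#'   `pos1`, `strand1`, `chrom2`, `pos2`, `strand2` (+ `replicate` if
#'   supplied), attribute `n_singletons`.
#' @export
pair_ends <- function(ends) {
  stopifnot(all(c("read_id", "chrom", "pos", "strand") %in% names(ends)))
  dt <- data.table::as.data.table(ends)
  has_rep <- "replicate" %in% names(dt)
  cnt <- dt[, .N, by = read_id]
  if (any(cnt$N > 2L))
    stop("read_id with more than two mapped ends: ",
         cnt$read_id[which(cnt$N > 2L)[1L]])
  n_singletons <- sum(cnt$N == 1L)
  dt <- dt[read_id %chin% cnt[N == 2L, read_id]]
  if (nrow(dt) == 0L) {
    out <- data.frame(read_id = character(), chrom1 = character(),
                      pos1 = integer(), strand1 = character(),
                      chrom2 = character(), pos2 = integer(),
                      strand2 = character())
    if (has_rep) out$replicate <- character()
  } else {
    data.table::setorder(dt, read_id, chrom, pos, strand)
    dt[, idx := seq_len(.N), by = read_id]
    keep <- c("read_id", if (has_rep) "replicate")
    wide <- dt[idx == 1L, c(keep, "chrom", "pos", "strand"), with = FALSE]
    data.table::setnames(wide, c("chrom", "pos", "strand"),
                         c("chrom1", "pos1", "strand1"))
    e2 <- dt[idx == 2L, .(read_id, chrom2 = chrom, pos2 = pos, strand2 = strand)]
    wide <- merge(wide, e2, by = "read_id", sort = TRUE)
    out <- as.data.frame(wide)
  }
  attr(out, "n_singletons") <- n_singletons
  class(out) <- c("hicap_pairs", "data.frame")
  out
}

#' Mark PCR-duplicate read pairs
#'
#' Pairs whose two ends have identical (chrom, pos, strand) on both sides are
#' duplicates; exactly one representative per identity is retained unmarked.
#' Deduplication is per replicate when a `replicate` column is present.
#' Idempotent.
#'
#' @param pairs a `hicap_pairs` data.frame (canonically ordered ends).
#' @return `pairs` with a logical `duplicate` column.
#' @export
dedupe_pairs <- function(pairs) {
  dt <- data.table::as.data.table(pairs)
  keycols <- c(if ("replicate" %in% names(dt)) "replicate",
               "chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")
  dt[, duplicate := duplicated(dt, by = keycols)]
  out <- as.data.frame(dt)
  attr(out, "n_singletons") <- attr(pairs, "n_singletons")
  class(out) <- c("hicap_pairs", "data.frame")
  out
}

#' Classify read pairs for Hi-C validity
#'
#' Assigns each pair its restriction fragments and a validity class:
#' `duplicate` (if flagged by [dedupe_pairs()]), `same_fragment` (both ends in
#' one fragment: self-ligation/un-ligated products), `too_close` (same
#' chromosome, ends < `min_distance` bp apart: residual self-ligation), else
#' `valid`. Trans-chromosomal pairs have no defined distance and are never
#' `too_close`. Classification is symmetric in end order.
#'
#' @param pairs a `hicap_pairs` data.frame, optionally after [dedupe_pairs()].
#' @param fragmap a `hicap_fragmap`.
#' @param min_distance minimum intra-chromosomal end separation in bp
#'   (default 1000, the 1-kb self-ligation filter).
#' @return `pairs` with `frag1`, `frag2` and `validity_class` columns.
#' @export
classify_pairs <- function(pairs, fragmap, min_distance = 1000L) {
  dt <- data.table::as.data.table(pairs)
  if (nrow(dt) == 0L) {
    dt[, `:=`(frag1 = integer(), frag2 = integer(),
              validity_class = character())]
  } else {
    dt[, frag1 := locate_fragment(fragmap, chrom1, pos1)$frag_id]
    dt[, frag2 := locate_fragment(fragmap, chrom2, pos2)$frag_id]
    cls <- rep("valid", nrow(dt))
    cls[dt$chrom1 == dt$chrom2 &
          abs(dt$pos1 - dt$pos2) < min_distance] <- "too_close"
    cls[dt$frag1 == dt$frag2] <- "same_fragment"
    if ("duplicate" %in% names(dt)) cls[dt$duplicate] <- "duplicate"
    dt[, validity_class := cls]
  }
  out <- as.data.frame(dt)
  attr(out, "n_singletons") <- attr(pairs, "n_singletons")
  class(out) <- c("hicap_pairs", "data.frame")
  out
}

#' Keep pairs with at least one end on a probe-target region
#'
#' Annotates each valid pair with the promoter id(s) whose probe targets
#' contain each end position, drops pairs with neither end on target
#' (class `off_target`), and flags promoter-promoter candidates (both ends on
#' targets). The full class accounting, including `off_target`, is attached
#' as attribute `class_counts` so that input pairs are conserved across
#' filter classes.
#'
#' @param pairs classified pairs (from [classify_pairs()]).
#' @param probes a `hicap_probes` data.frame.
#' @return retained pairs (validity_class `"valid"`, >= 1 end on target) with
#'   columns `promoter1`, `promoter2` (comma-separated promoter ids or `NA`)
#'   and `pp_candidate`; attribute `class_counts`.
#' @export
on_target_filter <- function(pairs, probes) {
  dt <- data.table::as.data.table(pairs)
  p1 <- rep(NA_character_, nrow(dt)); p2 <- p1
  if (nrow(dt) > 0L) {
    ov1 <- point_overlaps(dt$chrom1, dt$pos1, probes)
    ov2 <- point_overlaps(dt$chrom2, dt$pos2, probes)
    collapse <- function(ix) {
      if (is.null(ix)) NA_character_ else
        paste(unique(unlist(strsplit(probes$promoter_id[ix], ",", fixed = TRUE))),
              collapse = ",")
    }
    p1 <- vapply(ov1, collapse, character(1))
    p2 <- vapply(ov2, collapse, character(1))
  }
  dt[, promoter1 := p1]
  dt[, promoter2 := p2]
  on1 <- !is.na(p1); on2 <- !is.na(p2)
  valid <- dt$validity_class == "valid"
  counts <- c(table(dt$validity_class)[setdiff(unique(dt$validity_class), "valid")],
              off_target = sum(valid & !on1 & !on2),
              retained = sum(valid & (on1 | on2)))
  keep <- valid & (on1 | on2)
  out <- dt[keep]
  out[, pp_candidate := !is.na(promoter1) & !is.na(promoter2)]
  out <- as.data.frame(out)
  attr(out, "class_counts") <- counts
  class(out) <- c("hicap_pairs", "data.frame")
  out
}

#' Run the full pair-filtering cascade
#'
#' Convenience wrapper: [dedupe_pairs()] then [classify_pairs()] then
#' [on_target_filter()], returning the retained pairs and the class-count
#' accounting (input = retained + duplicate + same_fragment + too_close +
#' off_target).
#'
#' @inheritParams classify_pairs
#' @inheritParams on_target_filter
#' @return list with elements `pairs` (retained) and `counts` (named vector,
#'   including `input`).
#' @export
filter_pairs <- function(pairs, fragmap, probes, min_distance = 1000L) {
  n_in <- nrow(pairs)
  x <- on_target_filter(
    classify_pairs(dedupe_pairs(pairs), fragmap, min_distance), probes)
  counts <- attr(x, "class_counts")
  counts <- c(input = n_in, counts)
  list(pairs = x, counts = counts)
}

#' Capture efficiency statistics
#'
#' On-target fraction of aligned read ends and the corresponding fold
#' enrichment over the genomic share of the (unioned) target regions. With
#' target regions covering 0.4 % of the genome, an on-target fraction of 18 %
#' corresponds to 45-fold enrichment, and 44 % to 110-fold.
#'
#' @param ends data.frame of aligned ends (`chrom`, `pos`).
#' @param probes a `hicap_probes` data.frame (overlapping regions are
#'   unioned before measuring target bp).
#' @param genome_size total genome size in bp.
#' @return list: `on_target_fraction`, `target_fraction`, `fold_enrichment`.
#' @export
capture_stats <- function(ends, probes, genome_size) {
  stopifnot(genome_size > 0, nrow(probes) > 0)
  if (nrow(ends) == 0L) stop("no aligned ends")
  ## union of target regions per chromosome
  target_bp <- 0L
  merged <- list()
  for (cc in unique(probes$chrom)) {
    ri <- which(probes$chrom == cc)
    red <- IRanges::reduce(IRanges::IRanges(start = probes$start[ri] + 1L,
                                            end = probes$end[ri]))
    target_bp <- target_bp + sum(IRanges::width(red))
    merged[[cc]] <- data.frame(chrom = cc,
                               start = BiocGenerics::start(red) - 1L,
                               end = BiocGenerics::end(red))
  }
  merged <- do.call(rbind, merged)
  hits <- point_overlaps(ends$chrom, ends$pos, merged)
  frac <- mean(!vapply(hits, is.null, logical(1)))
  share <- target_bp / genome_size
  list(on_target_fraction = frac,
       target_fraction = share,
       fold_enrichment = frac / share)
}
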