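#' Count read-pair support per (promoter, partner fragment) per replicate
#'
#' For each retained pair, the on-target end maps to its promoter id(s) via
#' the probe-target regions and the other end to its restriction fragment;
#' counts accumulate per replicate. Pairs with both ends on promoter targets
#' accumulate into promoter-promoter (PP) counts under one canonical key;
#' pairs with exactly one on-target end accumulate into promoter-distal (PD)
#' counts. An end inside a shared target region counts for every promoter the
#' region belongs to.
#'
#' @param pairs retained pairs from [on_target_filter()] / [filter_pairs()]
#'   (must carry `promoter1`, `promoter2`, `frag1`, `frag2`; `replicate`
#'   optional, defaulting to one replicate `"rep1"`).
#' @return data.table in long form: `anchor`, `partner`, `type`
#'   (`"PD"`/`"PP"`), `replicate`, `n`. For PD, `partner` is the fragment id
#'   as `"F<frag_id>"`; for PP it is the second promoter id.
#' @export
count_support <- function(pairs) {
  dt <- data.table::as.data.table(pairs)
  if (!"replicate" %in% names(dt)) dt[, replicate := "rep1"]
  if (nrow(dt) == 0L)
    return(data.table::data.table(anchor = character(), partner = character(),
                                  type = character(), replicate = character(),
                                  n = integer()))
  on1 <- !is.na(dt$promoter1); on2 <- !is.na(dt$promoter2)
  pd <- xor(on1, on2); pp <- on1 & on2
  recs <- list()
  if (any(pd)) {
    proms <- ifelse(on1[pd], dt$promoter1[pd], dt$promoter2[pd])
    frag <- ifelse(on1[pd], dt$frag2[pd], dt$frag1[pd])
    sp <- strsplit(proms, ",", fixed = TRUE)
    k <- lengths(sp)
    recs$pd <- data.table::data.table(
      anchor = unlist(sp), partner = rep(paste0("F", frag), k),
      type = "PD", replicate = rep(dt$replicate[pd], k))
  }
  if (any(pp)) {
    a <- strsplit(dt$promoter1[pp], ",", fixed = TRUE)
    b <- strsplit(dt$promoter2[pp], ",", fixed = TRUE)
    cross <- mapply(function(x, y) {
      g <- expand.grid(a = x, b = y, stringsAsFactors = FALSE)
      g[g$a != g$b, , drop = FALSE]
    }, a, b, SIMPLIFY = FALSE)
    k <- vapply(cross, nrow, integer(1))
    g <- do.call(rbind, cross)
    if (nrow(g) > 0L)
      recs$pp <- data.table::data.table(
        anchor = pmin(g$a, g$b), partner = pmax(g$a, g$b),
        type = "PP", replicate = rep(dt$replicate[pp], k))
  }
  long <- data.table::rbindlist(recs)
  if (nrow(long) == 0L)
    return(data.table::data.table(anchor = character(), partner = character(),
                                  type = character(), replicate = character(),
                                  n = integer()))
  long[, .(n = .N), by = .(anchor, partner, type, replicate)]
}

## promoter id -> anchor region (bounding box over its probe targets) + gene
promoter_regions <- function(probes) {
  px <- data.table::as.data.table(expand_probes(probes))
  px[, .(chrom = chrom[1L], start = min(start), end = max(end),
         gene_id = gene_id[1L]), by = promoter_id]
}

#' Call interactions from per-replicate support counts
#'
#' Emits an interaction call for every (anchor, partner) whose read support
#' is at least `min_support` in *every* replicate — the fixed
#' three-reads-in-both-replicates rule at its default. Coordinates are
#' attached (promoter anchors get the bounding region of their probe
#' targets, distal partners their restriction fragment) and the interaction
#' distance is the absolute difference of region midpoints on the same
#' chromosome (`NA` with `trans = TRUE` otherwise).
#'
#' @param counts long-form counts from [count_support()] (or any table with
#'   `anchor`, `partner`, `type`, `replicate`, `n`).
#' @param probes a `hicap_probes` data.frame (anchor coordinates).
#' @param fragmap a `hicap_fragmap` (partner fragment coordinates).
#' @param min_support minimum read pairs per replicate (default 3).
#' @param replicates replicate labels that must all meet the threshold;
#'   default: every label present in `counts`. A replicate absent for a
#'   given (anchor, partner) counts as 0.
#' @return a `hicap_calls` data.frame: `anchor`, `anchor_gene`, `partner`,
#'   `type`, coordinates of both sides, `distance`, `trans`, and one
#'   `supp_<replicate>` column per replicate.
#' @export
call_interactions <- function(counts, probes, fragmap, min_support = 3L,
                              replicates = NULL) {
  dt <- data.table::as.data.table(counts)
  if (is.null(replicates))
    replicates <- sort(unique(dt$replicate))
  if (length(replicates) == 0L) replicates <- "rep1"
  wide <- data.table::dcast(dt, anchor + partner + type ~ replicate,
                            value.var = "n", fill = 0L)
  missing_rep <- setdiff(replicates, names(wide))
  for (m in missing_rep) wide[, (m) := 0L]
  supp <- as.matrix(wide[, replicates, with = FALSE])
  keep <- if (nrow(wide)) apply(supp >= min_support, 1L, all) else logical(0)
  wide <- wide[keep]; supp <- supp[keep, , drop = FALSE]

  pr <- promoter_regions(probes)
  data.table::setkey(pr, promoter_id)
  a <- pr[wide$anchor]
  ## partner: fragment for PD, promoter region for PP
  b_chrom <- character(nrow(wide)); b_start <- integer(nrow(wide))
  b_end <- integer(nrow(wide)); b_gene <- rep(NA_character_, nrow(wide))
  is_pd <- wide$type == "PD"
  if (any(is_pd)) {
    fid <- as.integer(sub("^F", "", wide$partner[is_pd]))
    fi <- match(fid, fragmap$frag_id)
    b_chrom[is_pd] <- fragmap$chrom[fi]
    b_start[is_pd] <- fragmap$start[fi]
    b_end[is_pd] <- fragmap$end[fi]
  }
  if (any(!is_pd)) {
    pb <- pr[wide$partner[!is_pd]]
    b_chrom[!is_pd] <- pb$chrom; b_start[!is_pd] <- pb$start
    b_end[!is_pd] <- pb$end; b_gene[!is_pd] <- pb$gene_id
  }
  mid_a <- (a$start + a$end) / 2
  mid_b <- (b_start + b_end) / 2
  trans <- a$chrom != b_chrom
  dist <- ifelse(trans, NA_real_, abs(mid_b - mid_a))

  out <- data.frame(
    anchor = wide$anchor, anchor_gene = a$gene_id,
    partner = wide$partner, partner_gene = b_gene, type = wide$type,
    chrom_a = a$chrom, start_a = a$start, end_a = a$end,
    chrom_b = b_chrom, start_b = b_start, end_b = b_end,
    distance = dist, trans = trans, stringsAsFactors = FALSE
  )
  colnames(supp) <- paste0("supp_", replicates)
  out <- cbind(out, as.data.frame(supp))
  rownames(out) <- NULL
  attr(out, "replicates") <- replicates
  attr(out, "min_support") <- min_support
  class(out) <- c("hicap_calls", "data.frame")
  out
}

#' Call distal-distal interactions
#'
#' Mines the (deduplicated, valid) read pairs for interactions with both
#' ends in distal fragments already seen as partners of called
#' promoter-distal interactions, applying the same per-replicate support
#' threshold.
#'
#' @param pairs classified pairs (pre on-target filtering; only
#'   `validity_class == "valid"` rows are used).
#' @param calls a `hicap_calls` set containing PD calls.
#' @param fragmap a `hicap_fragmap`.
#' @param min_support minimum read pairs per replicate (default 3).
#' @param replicates replicate labels; default those of `calls`.
#' @return a `hicap_calls` data.frame of type `"DD"` calls (anchor = lower
#'   fragment id).
#' @export
call_dd <- function(pairs, calls, fragmap, min_support = 3L,
                    replicates = NULL) {
  if (is.null(replicates)) replicates <- attr(calls, "replicates")
  distal <- unique(as.integer(sub("^F", "",
                                  calls$partner[calls$type == "PD"])))
  dt <- data.table::as.data.table(pairs)
  if (!"replicate" %in% names(dt)) dt[, replicate := "rep1"]
  dt <- dt[validity_class == "valid" & frag1 %in% distal & frag2 %in% distal &
             frag1 != frag2]
  empty <- function() {
    out <- data.frame(anchor = character(), anchor_gene = character(),
                      partner = character(), partner_gene = character(),
                      type = character(),
                      chrom_a = character(), start_a = integer(),
                      end_a = integer(), chrom_b = character(),
                      start_b = integer(), end_b = integer(),
                      distance = numeric(), trans = logical())
    for (r in replicates) out[[paste0("supp_", r)]] <- integer()
    attr(out, "replicates") <- replicates
    class(out) <- c("hicap_calls", "data.frame")
    out
  }
  if (length(distal) == 0L || nrow(dt) == 0L) return(empty())
  dt[, `:=`(fa = pmin(frag1, frag2), fb = pmax(frag1, frag2))]
  long <- dt[, .(n = .N), by = .(fa, fb, replicate)]
  wide <- data.table::dcast(long, fa + fb ~ replicate, value.var = "n",
                            fill = 0L)
  for (m in setdiff(replicates, names(wide))) wide[, (m) := 0L]
  supp <- as.matrix(wide[, replicates, with = FALSE])
  keep <- apply(supp >= min_support, 1L, all)
  wide <- wide[keep]; supp <- supp[keep, , drop = FALSE]
  if (nrow(wide) == 0L) return(empty())

  ia <- match(wide$fa, fragmap$frag_id); ib <- match(wide$fb, fragmap$frag_id)
  trans <- fragmap$chrom[ia] != fragmap$chrom[ib]
  mid_a <- (fragmap$start[ia] + fragmap$end[ia]) / 2
  mid_b <- (fragmap$start[ib] + fragmap$end[ib]) / 2
  out <- data.frame(
    anchor = paste0("F", wide$fa), anchor_gene = NA_character_,
    partner = paste0("F", wide$fb), partner_gene = NA_character_,
    type = "DD",
    chrom_a = fragmap$chrom[ia], start_a = fragmap$start[ia],
    end_a = fragmap$end[ia],
    chrom_b = fragmap$chrom[ib], start_b = fragmap$start[ib],
    end_b = fragmap$end[ib],
    distance = ifelse(trans, NA_real_, abs(mid_b - mid_a)),
    trans = trans, stringsAsFactors = FALSE
  )
  colnames(supp) <- paste0("supp_", replicates)
  out <- cbind(out, as.data.frame(supp))
  rownames(out) <- NULL
  attr(out, "replicates") <- replicates
  attr(out, "min_support") <- min_support
  class(out) <- c("hicap_calls", "data.frame")
  out
}

#' Annotate promoter-distal calls with the closest gene
#'
#' For each cis promoter-distal call, finds the gene whose TSS is nearest to
#' the distal fragment midpoint (ties broken toward the lower-coordinate
#' TSS) and flags whether that gene is the interacting gene itself. Trans
#' calls are left unannotated.
#'
#' @param calls a `hicap_calls` data.frame.
#' @param tss_table data.frame with `chrom`, `tss`, `gene_id`.
#' @return `calls` with `closest_gene` and `closest_gene_flag` columns.
#' @export
annotate_closest_gene <- function(calls, tss_table) {
  calls$closest_gene <- NA_character_
  calls$closest_gene_flag <- NA
  idx <- which(calls$type == "PD" & !calls$trans)
  if (length(idx) == 0L) return(calls)
  mid <- (calls$start_b[idx] + calls$end_b[idx]) / 2
  calls$closest_gene[idx] <- nearest_tss_gene(calls$chrom_b[idx], mid,
                                              tss_table)
  calls$closest_gene_flag[idx] <-
    calls$closest_gene[idx] == calls$anchor_gene[idx]
  calls
}

## nearest TSS gene per (chrom, position); tie -> lower-coordinate TSS
nearest_tss_gene <- function(chrom, pos, tss_table) {
  out <- rep(NA_character_, length(pos))
  for (cc in unique(chrom)) {
    qi <- which(chrom == cc)
    ti <- which(tss_table$chrom == cc)
    if (length(ti) == 0L) next
    ord <- ti[order(tss_table$tss[ti])]
    tp <- tss_table$tss[ord]
    right <- findInterval(pos[qi], tp) + 1L   # first TSS at/after pos
    left <- right - 1L
    pick <- integer(length(qi))
    for (k in seq_along(qi)) {
      l <- left[k]; r <- right[k]
      dl <- if (l >= 1L) abs(pos[qi][k] - tp[l]) else Inf
      dr <- if (r <= length(tp)) abs(tp[r] - pos[qi][k]) else Inf
      pick[k] <- if (dl <= dr) l else r    # tie -> left (lower coordinate)
    }
    out[qi] <- tss_table$gene_id[ord[pick]]
  }
  out
}
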