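#' In-silico restriction digestion of a genome
#'
#' Scans each chromosome for occurrences of the enzyme recognition site and
#' builds the restriction fragment map. The cut position is the 0-based start
#' of every site occurrence (MboI cuts `^GATC`, leaving the site on the
#' downstream fragment); fragments span between consecutive cuts and the
#' chromosome ends. A site occurrence at position 0 would create an empty
#' leading fragment and is suppressed. `N` bases never match the site, so
#' N-runs simply contain no cuts.
#'
#' A 4-bp cutter such as MboI has a theoretical mean fragment size of
#' 4^4 = 256 bp under uniform base composition (422 bp in the GC-biased mouse
#' genome), which is what makes fragment-level promoter-interaction mapping
#' possible.
#'
#' @param genome named character vector of chromosome sequences, or a
#'   `Biostrings::DNAStringSet`. Names must be unique, sequences non-empty.
#' @param site recognition sequence, a non-empty string over A/C/G/T
#'   (default `"GATC"`, MboI).
#' @return a `hicap_fragmap`: a data.frame with columns `chrom`, `start`,
#'   `end` (0-based half-open), `frag_id` (integer, unique genome-wide), with
#'   attributes `chrom_lengths` (named integer) and `site`. Fragments tile
#'   each chromosome exactly: non-overlapping, sorted, no zero-length
#'   fragments.
#' @examples
#' fm <- digest_genome(c(chrA = "TTTTGATCAAAAGATCCC"))
#' fm[, c("start", "end")]   # fragments [0,4) [4,12) [12,18)
#' @export
digest_genome <- function(genome, site = "GATC") {
  if (is.character(genome)) {
    if (is.null(names(genome)) || any(!nzchar(names(genome))))
      stop("genome sequences must be named by chromosome")
    genome <- Biostrings::DNAStringSet(genome)
  }
  if (!methods::is(genome, "DNAStringSet"))
    stop("genome must be a named character vector or DNAStringSet")
  if (length(genome) == 0L) stop("empty genome")
  if (anyDuplicated(names(genome))) stop("duplicated chromosome names")
  lens <- Biostrings::width(genome)
  if (any(lens == 0L)) stop("zero-length chromosome in genome")
  if (!grepl("^[ACGT]+$", site))
    stop("recognition site must be a non-empty string over A/C/G/T")

  hits <- Biostrings::vmatchPattern(site, genome)
  out <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    cuts <- BiocGenerics::start(hits[[i]]) - 1L      # 0-based cut positions
    cuts <- cuts[cuts > 0L]                           # suppress empty leading fragment
    bounds <- c(0L, sort(cuts), lens[i])
    out[[i]] <- data.frame(
      chrom = names(genome)[i],
      start = bounds[-length(bounds)],
      end   = bounds[-1L],
      stringsAsFactors = FALSE
    )
  }
  fm <- do.call(rbind, out)
  rownames(fm) <- NULL
  fm$frag_id <- seq_len(nrow(fm))
  attr(fm, "chrom_lengths") <- stats::setNames(as.integer(lens), names(genome))
  attr(fm, "site") <- site
  class(fm) <- c("hicap_fragmap", "data.frame")
  fm
}

#' Mean restriction fragment length
#'
#' Arithmetic mean of fragment lengths over all chromosomes of a fragment map.
#'
#' @param fragmap a `hicap_fragmap` from [digest_genome()].
#' @return mean fragment length in bp.
#' @export
mean_fragment_length <- function(fragmap) {
  stopifnot(nrow(fragmap) > 0L)
  mean(fragmap$end - fragmap$start)
}

#' Locate the fragment containing each genomic position
#'
#' Point query into a fragment map: returns, for each `(chrom, pos)` pair,
#' the unique fragment with `start <= pos < end`.
#'
#' @param fragmap a `hicap_fragmap`.
#' @param chrom chromosome names (recycled against `pos`).
#' @param pos 0-based positions, each within `[0, chrom_length)`.
#' @return data.frame of fragment rows (`chrom`, `start`, `end`, `frag_id`),
#'   one per query.
#' @export
locate_fragment <- function(fragmap, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  lens <- attr(fragmap, "chrom_lengths")
  row <- integer(n)
  for (cc in unique(chrom)) {
    qi <- which(chrom == cc)
    fi <- which(fragmap$chrom == cc)
    if (length(fi) == 0L) stop("chromosome not in fragment map: ", cc)
    if (any(pos[qi] < 0L | pos[qi] >= lens[[cc]]))
      stop("position out of range on ", cc)
    row[qi] <- fi[findInterval(pos[qi], fragmap$start[fi])]
  }
  out <- fragmap[row, c("chrom", "start", "end", "frag_id")]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' Design promoter probe-target regions
#'
#' For each transcription start site, locates the closest restriction cut
#' site upstream and downstream (the boundaries of the TSS's fragment). When
#' the two cuts are less than `merge_below` bp apart, the whole inter-cut
#' region is one target; otherwise two targets of `flank` bp are emitted, one
#' abutting each cut on the TSS-facing (fragment-interior) side. A TSS whose
#' fragment touches a chromosome end lacks a cut on that side; the target is
#' clipped to the chromosome end and flagged. Identical regions arising from
#' TSSs that share flanking cuts are emitted once, with all promoter and gene
#' ids attached (comma-separated).
#'
#' @param tss_table data.frame with columns `chrom`, `tss` (0-based
#'   position), `promoter_id`, `gene_id`, and optionally `control` (logical,
#'   negative-control regions).
#' @param fragmap a `hicap_fragmap`; every TSS chromosome must be present.
#' @param flank captured bp adjacent to each cut site (default 150).
#' @param merge_below if the flanking cuts are closer than this, capture the
#'   whole inter-cut region as one target (default 300).
#' @return a `hicap_probes` data.frame: `chrom`, `start`, `end`,
#'   `promoter_id`, `gene_id`, `tss`, `control`, `clipped`.
#' @export
design_probe_targets <- function(tss_table, fragmap, flank = 150L,
                                 merge_below = 300L) {
  stopifnot(all(c("chrom", "tss", "promoter_id", "gene_id") %in%
                  names(tss_table)))
  if (nrow(tss_table) == 0L) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      promoter_id = character(), gene_id = character(),
                      tss = integer(), control = logical(), clipped = logical())
    class(out) <- c("hicap_probes", "data.frame")
    return(out)
  }
  lens <- attr(fragmap, "chrom_lengths")
  frag <- locate_fragment(fragmap, tss_table$chrom, tss_table$tss)
  ctrl <- if ("control" %in% names(tss_table)) tss_table$control else
    rep(FALSE, nrow(tss_table))

  rows <- vector("list", nrow(tss_table))
  for (i in seq_len(nrow(tss_table))) {
    s <- frag$start[i]; e <- frag$end[i]; cc <- frag$chrom[i]
    clipped <- (s == 0L) || (e == lens[[cc]])   # missing cut on one side
    if ((e - s) < merge_below) {
      tg <- data.frame(chrom = cc, start = s, end = e)
    } else {
      tg <- data.frame(chrom = cc,
                       start = c(s, max(e - flank, s)),
                       end   = c(min(s + flank, e), e))
    }
    tg$promoter_id <- tss_table$promoter_id[i]
    tg$gene_id <- tss_table$gene_id[i]
    tg$tss <- tss_table$tss[i]
    tg$control <- ctrl[i]
    tg$clipped <- clipped
    rows[[i]] <- tg
  }
  dt <- data.table::rbindlist(rows)
  ## deduplicate identical regions, attaching all promoter/gene ids
  dt <- dt[, {
    u <- unique(data.table::data.table(promoter_id, gene_id))
    .(promoter_id = paste(u$promoter_id, collapse = ","),
      gene_id = paste(u$gene_id, collapse = ","),  # parallel to promoter_id
      tss = tss[1L], control = any(control), clipped = any(clipped))
  }, by = .(chrom, start, end)]
  data.table::setorder(dt, chrom, start, end)
  out <- as.data.frame(dt)
  class(out) <- c("hicap_probes", "data.frame")
  out
}

## promoter_id -> one row per (region, single promoter id); used by the
## counting and capture-statistics code.
expand_probes <- function(probes) {
  dt <- data.table::as.data.table(probes)
  dt <- dt[, {
    p <- strsplit(promoter_id, ",", fixed = TRUE)[[1L]]
    g <- strsplit(gene_id, ",", fixed = TRUE)[[1L]]
    .(promoter_id = p, gene_id = rep_len(g, length(p)))
  }, by = .(chrom, start, end, control)]
  as.data.frame(dt)
}
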