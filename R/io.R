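#' Read a genome from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)),
                  sub("\\s.*$", "", names(x)))
}

#' Write a genome to FASTA
#' @param genome named character vector of sequences.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Read/write BED-like interval tables (0-based half-open, as BED itself)
#'
#' `read_bed` maps columns 1-3 to `chrom`/`start`/`end`; column 4 becomes
#' `name` and column 5 `score` when present. `write_bed` writes the given
#' columns tab-separated without headers.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  data.table::setnames(dt, seq_len(min(ncol(dt), 6L)),
                       cols[seq_len(min(ncol(dt), 6L))])
  as.data.frame(dt)
}

#' @rdname read_bed
#' @param x interval data.frame; first columns written are
#'   `chrom`, `start`, `end`, then any of `name`, `score`, `strand` present.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  data.table::fwrite(x[, cols, drop = FALSE], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Fragment map BED round-trip
#'
#' The fragment map is exchanged as BED4 with the fragment id in the name
#' column; `read_fragmap_bed` restores the `hicap_fragmap` attributes
#' (chromosome lengths are taken as each chromosome's last fragment end).
#'
#' @param fragmap a `hicap_fragmap`.
#' @param path file path.
#' @export
write_fragmap_bed <- function(fragmap, path) {
  x <- data.frame(chrom = fragmap$chrom, start = fragmap$start,
                  end = fragmap$end, name = fragmap$frag_id)
  write_bed(x, path)
}

#' @rdname write_fragmap_bed
#' @export
read_fragmap_bed <- function(path) {
  x <- read_bed(path)
  fm <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                   frag_id = as.integer(x$name), stringsAsFactors = FALSE)
  lens <- tapply(fm$end, fm$chrom, max)
  attr(fm, "chrom_lengths") <- stats::setNames(as.integer(lens), names(lens))
  class(fm) <- c("hicap_fragmap", "data.frame")
  fm
}

#' Probe-target BED6 round-trip (name = promoter_id|gene_id)
#' @param probes a `hicap_probes` data.frame.
#' @param path file path.
#' @export
write_probes_bed <- function(probes, path) {
  x <- data.frame(chrom = probes$chrom, start = probes$start,
                  end = probes$end,
                  name = paste(probes$promoter_id, probes$gene_id, sep = "|"),
                  score = as.integer(probes$control),
                  strand = ifelse(probes$clipped, "-", "+"))
  write_bed(x, path)
}

#' @rdname write_probes_bed
#' @export
read_probes_bed <- function(path) {
  x <- read_bed(path)
  parts <- strsplit(x$name, "|", fixed = TRUE)
  out <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                    promoter_id = vapply(parts, `[`, character(1), 1L),
                    gene_id = vapply(parts, `[`, character(1), 2L),
                    tss = NA_integer_,
                    control = x$score == 1L,
                    clipped = x$strand == "-", stringsAsFactors = FALSE)
  class(out) <- c("hicap_probes", "data.frame")
  out
}

#' Interaction calls TSV round-trip
#' @param calls a `hicap_calls` data.frame.
#' @param path file path.
#' @export
write_calls_tsv <- function(calls, path) {
  data.table::fwrite(as.data.frame(calls), path, sep = "\t", na = "NA")
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
read_calls_tsv <- function(path) {
  x <- as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
  for (col in intersect(c("anchor_gene", "partner_gene", "closest_gene"),
                        names(x)))
    x[[col]] <- as.character(x[[col]])
  attr(x, "replicates") <- sub("^supp_", "",
                               grep("^supp_", names(x), value = TRUE))
  class(x) <- c("hicap_calls", "data.frame")
  x
}

#' Export interaction calls as GFF for genome-browser display
#'
#' One feature per interaction side, sharing a group id, so paired anchors
#' can be displayed together (GFF2 group syntax).
#'
#' @param calls a `hicap_calls` data.frame.
#' @param path output file.
#' @export
write_calls_gff <- function(calls, path) {
  gid <- sprintf("int%06d", seq_len(nrow(calls)))
  lines <- c(
    sprintf("%s\thicap\tinteraction\t%d\t%d\t.\t.\t.\tgroup %s; anchor %s",
            calls$chrom_a, calls$start_a + 1L, calls$end_a, gid,
            calls$anchor),
    sprintf("%s\thicap\tinteraction\t%d\t%d\t.\t.\t.\tgroup %s; partner %s",
            calls$chrom_b, calls$start_b + 1L, calls$end_b, gid,
            calls$partner))
  writeLines(lines, path)
  invisible(path)
}

#' Read aligned ends from TSV (read_id, chrom, pos, strand[, replicate])
#' @param path file path.
#' @param replicate optional replicate label to attach.
#' @export
read_ends_tsv <- function(path, replicate = NULL) {
  x <- as.data.frame(data.table::fread(path, sep = "\t"))
  stopifnot(all(c("read_id", "chrom", "pos", "strand") %in% names(x)))
  if (!is.null(replicate)) x$replicate <- replicate
  x
}

#' Read a simple key: value configuration file
#'
#' One `key: value` pair per line; `#` comments and blank lines ignored.
#' Values that parse as numbers become numeric.
#'
#' @param path configuration file.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  out <- list()
  for (m in kv) {
    if (length(m) == 3L) {
      v <- trimws(m[3L])
      num <- suppressWarnings(as.numeric(v))
      out[[trimws(m[2L])]] <- if (!is.na(num)) num else v
    }
  }
  out
}
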