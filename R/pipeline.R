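#' Run the capture Hi-C pipeline end to end
#'
#' Executes digestion, probe design, pair filtering and interaction calling
#' (promoter-distal, promoter-promoter and distal-distal), writing versioned
#' tab-separated outputs plus a run log with every parameter and the
#' filter-class accounting. When `simulate = TRUE` (default when no input
#' paths are given), inputs are generated by the simulator and a
#' ground-truth comparison report is included.
#'
#' @param out_dir output directory (created if needed).
#' @param cfg a [sim_config()] used when simulating; ignored otherwise.
#' @param seed integer seed driving all randomness (mandatory).
#' @param genome named character vector of sequences; when `NULL`, a
#'   genome is simulated from `cfg`.
#' @param tss_table promoter table when supplying real inputs.
#' @param ends aligned-end table (`read_id`, `chrom`, `pos`, `strand`,
#'   `replicate`) when supplying real inputs.
#' @param site recognition sequence (default `"GATC"`).
#' @param flank,merge_below probe-design parameters (150 / 300 bp).
#' @param min_distance self-ligation distance filter (1000 bp).
#' @param min_support per-replicate read-support threshold (3).
#' @return invisibly, a list with `fragmap`, `probes`, `filtered`, `calls`
#'   (PD+PP), `dd_calls`, `counts`, and (when simulating) `truth` and
#'   `recovery` (precision/recall of planted loops).
#' @export
run_pipeline <- function(out_dir, cfg = sim_config(), seed,
                         genome = NULL, tss_table = NULL, ends = NULL,
                         site = "GATC", flank = 150L, merge_below = 300L,
                         min_distance = 1000L, min_support = 3L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  simulate <- is.null(genome)
  truth <- NULL
  if (simulate) {
    sim <- simulate_genome(cfg, seed)
    genome <- sim$genome
    tss_table <- sim$tss_table
  }
  fragmap <- digest_genome(genome, site = site)
  probes <- design_probe_targets(tss_table, fragmap, flank = flank,
                                 merge_below = merge_below)
  if (simulate) {
    rd <- simulate_reads(cfg, sim, fragmap, probes, seed = seed + 1L)
    ends <- rd$ends
    truth <- rd$truth
  }
  if (is.null(ends)) stop("missing input: aligned ends")

  pairs <- pair_ends(ends)
  classified <- classify_pairs(dedupe_pairs(pairs), fragmap, min_distance)
  filtered <- on_target_filter(classified, probes)
  counts <- c(input = nrow(pairs), attr(filtered, "class_counts"))

  support <- count_support(filtered)
  calls <- call_interactions(support, probes, fragmap,
                             min_support = min_support)
  dd <- call_dd(classified, calls, fragmap, min_support = min_support)

  write_fragmap_bed(fragmap, file.path(out_dir, "fragments.bed"))
  write_probes_bed(probes, file.path(out_dir, "probes.bed"))
  write_calls_tsv(calls, file.path(out_dir, "calls.tsv"))
  write_calls_tsv(dd, file.path(out_dir, "calls_dd.tsv"))
  write_calls_gff(calls, file.path(out_dir, "calls.gff"))

  recovery <- NULL
  if (simulate && !is.null(truth)) {
    recovery <- loop_recovery(calls, truth)
    data.table::fwrite(data.frame(metric = names(recovery),
                                  value = unlist(recovery)),
                       file.path(out_dir, "recovery.tsv"), sep = "\t")
  }
  log_lines <- c(
    sprintf("seed: %d", seed),
    sprintf("site: %s", site),
    sprintf("flank: %d", flank),
    sprintf("merge_below: %d", merge_below),
    sprintf("min_distance: %d", min_distance),
    sprintf("min_support: %d", min_support),
    sprintf("count_%s: %d", names(counts), as.integer(counts)),
    sprintf("calls_pd: %d", sum(calls$type == "PD")),
    sprintf("calls_pp: %d", sum(calls$type == "PP")),
    sprintf("calls_dd: %d", nrow(dd))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(fragmap = fragmap, probes = probes, filtered = filtered,
                 calls = calls, dd_calls = dd, counts = counts,
                 truth = truth, recovery = recovery))
}

#' Precision and recall of planted loops
#'
#' Compares called promoter-distal interactions against the planted
#' (promoter, distal fragment) ground truth.
#'
#' @param calls a `hicap_calls` set.
#' @param truth planted truth from [simulate_reads()].
#' @return list: `precision`, `recall`, `n_called`, `n_planted`.
#' @export
loop_recovery <- function(calls, truth) {
  called <- paste(calls$anchor[calls$type == "PD"],
                  calls$partner[calls$type == "PD"])
  planted <- paste(truth$loops$promoter_id,
                   paste0("F", truth$loops$frag_id))
  tp <- sum(called %in% planted)
  list(precision = if (length(called)) tp / length(called) else NA_real_,
       recall = if (length(planted)) tp / length(planted) else NA_real_,
       n_called = length(called), n_planted = length(planted))
}
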