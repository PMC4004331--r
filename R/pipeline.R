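#' Run the full cassette-to-statistics pipeline
#'
#' Convenience wrapper: merge detector predictions, apply the three-rule
#' consensus filter, extract spacers, cluster repeats, orient cassettes,
#' scan for protospacers (excluding all candidate intervals), apply the
#' repeat-contamination filter, flag targeting/shared spacers and build the
#' pair matrix. Intended for synthetic or modest-sized data; each stage is
#' also exported on its own.
#'
#' @param contigs contig table ([read_contigs()]).
#' @param predictions prediction table ([ingest_predictions_tsv()] or
#'   [emit_detector_predictions()]).
#' @param cas cas gene annotations ([read_cas_tsv()]), may be empty.
#' @param max_mismatches protospacer reliability threshold (default 4).
#' @param adjacency_window cas adjacency window, nt (default 2000).
#' @param min_flank completeness flank, nt (default 100).
#' @return list: `candidates`, `cassette_set` (with oriented cassettes and
#'   spacers), `clusters`, `hits` (all scanned), `reliable` (reliable hits),
#'   `spacers` (classified), `pair_matrix`.
#' @export
run_pipeline <- function(contigs, predictions, cas,
                         max_mismatches = 4L, adjacency_window = 2000L,
                         min_flank = 100L) {
  candidates <- merge_predictions(predictions)
  cassette_set <- consensus_filter(candidates, predictions, cas, contigs,
                                   adjacency_window = adjacency_window,
                                   min_flank = min_flank)
  cs <- cassette_set$cassettes
  clusters <- cluster_repeats(setNames(cs$repeat_consensus, cs$cassette_id))
  cassette_set <- orient_cassettes(cassette_set, cas, clusters,
                                   adjacency_window = adjacency_window)
  exclude <- rbind(candidates[c("contig_id", "start", "end")],
                   cs[c("contig_id", "start", "end")])
  hits <- scan_targets(cassette_set$spacers, contigs, exclude = exclude,
                       max_mismatches = max_mismatches)
  hits <- repeat_contamination_filter(hits, cs, contigs)
  rel <- reliable_hits(hits, max_mismatches)
  spacers <- classify_spacers(cassette_set$spacers, rel, contigs)
  cassette_set$spacers <- spacers
  pm <- build_pair_matrix(rel, spacers, contigs)
  list(candidates = candidates, cassette_set = cassette_set,
       clusters = clusters, hits = hits, reliable = rel,
       spacers = spacers, pair_matrix = pm)
}
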