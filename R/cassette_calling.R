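# Candidate construction and the three-rule consensus filter:
#   (1) arrays reported by all three detectors are accepted outright;
#   (2) arrays reported by one or two detectors are accepted when a cas gene
#       lies within the adjacency window on the same contig;
#   (3) remaining candidates whose repeat consensus falls in the same repeat
#       cluster as an already-accepted cassette are accepted; rule 3 is
#       iterated to a fixed point.

#' Minimal built-in CRISPR array detector
#'
#' Chains exact repeated k-mers (k = minimum repeat length) whose successive
#' start-to-start distances are admissible for a repeat-spacer period, then
#' extends repeat boundaries while all copies agree, up to the maximum repeat
#' length and keeping spacer gaps at least the minimum. Greedy
#' longest-chain-first with leftmost tie-breaking. Exists so synthetic
#' end-to-end runs need no external detector; it is not a reimplementation of
#' any published tool.
#'
#' @param contigs contig table (or a single row).
#' @param repeat_length integer pair, admissible repeat lengths (default
#'   21-48 nt).
#' @param spacer_gap integer pair, admissible spacer lengths (default
#'   20-80 nt).
#' @param min_copies minimum repeat copies per array (default 3).
#' @return prediction table (`program = "BUILTIN"`), possibly empty.
#' @export
detect_arrays_builtin <- function(contigs, repeat_length = c(21L, 48L),
                                  spacer_gap = c(20L, 80L), min_copies = 3L) {
  k <- as.integer(repeat_length[1])
  dmin <- repeat_length[1] + spacer_gap[1]
  dmax <- repeat_length[2] + spacer_gap[2]
  rows <- list()
  for (ci in seq_len(nrow(contigs))) {
    seq <- contigs$sequence[ci]
    n <- nchar(seq)
    if (n <= 2L * k) next
    starts <- seq_len(n - k + 1L)
    kmers <- substring(seq, starts, starts + k - 1L)
    reps <- split(starts, kmers)
    reps <- reps[lengths(reps) >= min_copies]
    cand <- list()
    for (pos in reps) {
      pos <- sort(pos)
      used <- rep(FALSE, length(pos))
      for (s0 in seq_along(pos)) {
        if (used[s0]) next
        chain <- pos[s0]
        repeat {
          nxt <- which(!used & pos > chain[length(chain)] &
                         pos - chain[length(chain)] >= dmin &
                         pos - chain[length(chain)] <= dmax)
          if (!length(nxt)) break
          chain <- c(chain, pos[nxt[1]])
          used[nxt[1]] <- TRUE
        }
        used[s0] <- TRUE
        if (length(chain) >= min_copies) cand[[length(cand) + 1]] <- chain
      }
    }
    if (!length(cand)) next
    # extend every chain to the maximal unanimous repeat block
    ext <- lapply(cand, function(chain) {
      m <- length(chain)
      s <- chain - 1L  # 0-based starts
      e <- s + k
      gap_ok <- function(s, e) {
        all(s[-1] - e[-m] >= spacer_gap[1])
      }
      ch1 <- function(p) substring(seq, p + 1L, p + 1L) # base at 0-based p
      while ((e[1] - s[1]) < repeat_length[2] && s[1] > 0L &&
             length(unique(ch1(s - 1L))) == 1L &&
             gap_ok(s - 1L, e)) s <- s - 1L
      while ((e[1] - s[1]) < repeat_length[2] && e[m] < n &&
             length(unique(ch1(e))) == 1L &&
             gap_ok(s, e + 1L)) e <- e + 1L
      list(s = s, e = e)
    })
    keys <- vapply(ext, function(x) paste(x$s, x$e, collapse = ";"), "")
    ext <- ext[!duplicated(keys)]
    # greedy: most copies, then longest span, then leftmost; drop overlaps
    ord <- order(-vapply(ext, function(x) length(x$s), 0L),
                 -vapply(ext, function(x) x$e[length(x$e)] - x$s[1], 0L),
                 vapply(ext, function(x) x$s[1], 0L))
    taken <- list()
    for (i in ord) {
      x <- ext[[i]]
      span <- c(x$s[1], x$e[length(x$e)])
      clash <- any(vapply(taken, function(t)
        span[1] < t[2] && t[1] < span[2], TRUE))
      if (clash) next
      taken[[length(taken) + 1]] <- span
      copies <- substring(seq, x$s + 1L, x$e)
      aid <- sprintf("B%d", length(taken))
      rows[[length(rows) + 1]] <- data.frame(
        prediction_id = paste(contigs$contig_id[ci], "BUILTIN", aid, sep = "/"),
        contig_id = contigs$contig_id[ci], program = "BUILTIN",
        start = x$s, end = x$e, consensus = consensus_repeat(copies),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(prediction_id = character(0), contig_id = character(0),
                      program = character(0), start = integer(0),
                      end = integer(0), consensus = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

prediction_spans <- function(predictions) {
  sp <- do.call(rbind, lapply(split(predictions, predictions$prediction_id),
    function(g) data.frame(
      prediction_id = g$prediction_id[1], contig_id = g$contig_id[1],
      program = g$program[1], start = min(g$start), end = max(g$end),
      n_repeats = nrow(g), consensus = g$consensus[1],
      stringsAsFactors = FALSE)))
  rownames(sp) <- NULL
  sp
}

#' Merge per-program predictions into candidate cassettes
#'
#' Arrays on the same contig whose spans reciprocally overlap by at least
#' `min_reciprocal` are grouped by single linkage. The candidate interval is
#' the union of member spans; the member with the most repeat copies (ties:
#' longest span, then leftmost) becomes the `best_prediction` that defines
#' repeat and spacer coordinates downstream.
#'
#' @param predictions prediction table.
#' @param min_reciprocal reciprocal overlap fraction (default 0.5).
#' @return candidate table: `candidate_id`, `contig_id`, `start`, `end`,
#'   `programs` (comma-separated), `best_prediction_id`, `n_predictions`,
#'   plus attribute `members` mapping predictions to candidates.
#' @export
merge_predictions <- function(predictions, min_reciprocal = 0.5) {
  if (nrow(predictions) == 0)
    return(data.frame(candidate_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      programs = character(0),
                      best_prediction_id = character(0),
                      n_predictions = integer(0)))
  sp <- prediction_spans(predictions)
  out <- list(); members <- list()
  for (cid in unique(sp$contig_id)) {
    g <- sp[sp$contig_id == cid, ]
    m <- nrow(g)
    comp <- seq_len(m)
    if (m > 1) {
      for (i in 1:(m - 1)) for (j in (i + 1):m) {
        ov <- min(g$end[i], g$end[j]) - max(g$start[i], g$start[j])
        if (ov <= 0) next
        if (ov / (g$end[i] - g$start[i]) >= min_reciprocal &&
            ov / (g$end[j] - g$start[j]) >= min_reciprocal) {
          old <- comp[j]; comp[comp == old] <- comp[i]
        }
      }
    }
    for (cc in unique(comp)) {
      idx <- which(comp == cc)
      gg <- g[idx, ]
      best <- gg[order(-gg$n_repeats, -(gg$end - gg$start), gg$start), ][1, ]
      out[[length(out) + 1]] <- data.frame(
        contig_id = cid, start = min(gg$start), end = max(gg$end),
        programs = paste(sort(unique(gg$program)), collapse = ","),
        best_prediction_id = best$prediction_id,
        n_predictions = nrow(gg), stringsAsFactors = FALSE)
      members[[length(members) + 1]] <- gg$prediction_id
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$contig_id, out$start), , drop = FALSE]
  out$candidate_id <- sprintf("CAND%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  attr(out, "members") <- setNames(members, out$candidate_id)
  out[c("candidate_id", "contig_id", "start", "end", "programs",
        "best_prediction_id", "n_predictions")]
}

has_programs <- function(programs, want) {
  vapply(strsplit(programs, ","), function(p) all(want %in% p), TRUE)
}

cas_near <- function(candidate, cas, window) {
  idx <- which(cas$contig_id == candidate$contig_id)
  if (!length(idx)) return(FALSE)
  gap <- pmax(cas$start[idx] - candidate$end, candidate$start - cas$end[idx], 0L)
  any(gap <= window)
}

#' Three-rule consensus filter
#'
#' Applies the acceptance rules in priority order (1 > 2 > 3, each candidate
#' gets exactly one rule) and builds the accepted cassette set. Repeat and
#' spacer coordinates come from each candidate's best prediction; the repeat
#' consensus is recomputed from the actual contig copies by majority vote.
#'
#' @param candidates output of [merge_predictions()].
#' @param predictions the prediction table the candidates came from.
#' @param cas cas gene annotations (0-based half-open), may be empty.
#' @param contigs contig table (sequences needed for consensus and spacers).
#' @param adjacency_window cas adjacency window in nt (default 2000).
#' @param min_flank non-cassette flank required on both sides for a cassette
#'   to count as complete (default 100 nt).
#' @param cluster_params identity/coverage/word-size parameters passed to
#'   [cluster_repeats()] for rule 3.
#' @return cassette set: list with `cassettes`, `repeats`, `spacers` (spacers
#'   filled by [extract_spacers()], which this calls), and `rejected`
#'   (candidate ids that passed no rule).
#' @export
consensus_filter <- function(candidates, predictions, cas, contigs,
                             adjacency_window = 2000L, min_flank = 100L,
                             cluster_params = list(min_identity = 0.5,
                                                   min_coverage = 0.5,
                                                   word_size = 15L)) {
  nc <- nrow(candidates)
  rule <- rep(NA_character_, nc)
  rule[has_programs(candidates$programs, c("CRT", "CFI", "PIL"))] <- "all_three"
  cas_adj <- vapply(seq_len(nc), function(i)
    cas_near(candidates[i, ], cas, adjacency_window), TRUE)
  rule[is.na(rule) & cas_adj] <- "cas_adjacent"

  # candidate repeat consensus (from contig copies of the best prediction)
  consensus_of <- function(i) {
    g <- predictions[predictions$prediction_id ==
                       candidates$best_prediction_id[i], ]
    seq <- contigs$sequence[match(g$contig_id[1], contigs$contig_id)]
    consensus_repeat(substring(seq, g$start + 1L, g$end))
  }
  consensi <- vapply(seq_len(nc), consensus_of, "")

  # rule 3 to a fixed point: with a fixed clustering of all candidate
  # consensi, acceptance propagates through whole clusters at once, which is
  # already the closure; iterate anyway to make the fixed point explicit.
  if (any(is.na(rule)) && any(!is.na(rule))) {
    cl <- cluster_repeats(setNames(consensi, candidates$candidate_id),
                          min_identity = cluster_params$min_identity,
                          min_coverage = cluster_params$min_coverage,
                          word_size = cluster_params$word_size)
    repeat {
      acc_cl <- unique(cl$cluster_id[!is.na(rule)])
      newly <- is.na(rule) & cl$cluster_id %in% acc_cl
      if (!any(newly)) break
      rule[newly] <- "repeat_similar"
    }
  }

  acc <- which(!is.na(rule))
  rows_c <- list(); rows_r <- list()
  for (i in acc) {
    g <- predictions[predictions$prediction_id ==
                       candidates$best_prediction_id[i], ]
    g <- g[order(g$start), ]
    contig <- contigs[match(g$contig_id[1], contigs$contig_id), ]
    cass_id <- candidates$candidate_id[i]
    s <- min(g$start); e <- max(g$end)
    rows_c[[length(rows_c) + 1]] <- data.frame(
      cassette_id = cass_id, contig_id = g$contig_id[1],
      start = s, end = e,
      repeat_consensus = consensi[i],
      programs = candidates$programs[i],
      acceptance_rule = rule[i],
      cas_adjacent = cas_adj[i],
      leader_end = "unknown",
      complete = (s >= min_flank) & (contig$length - e >= min_flank),
      stringsAsFactors = FALSE)
    rows_r[[length(rows_r) + 1]] <- data.frame(
      cassette_id = cass_id, contig_id = g$contig_id[1],
      start = g$start, end = g$end, stringsAsFactors = FALSE)
  }
  cassettes <- if (length(rows_c)) do.call(rbind, rows_c) else
    data.frame(cassette_id = character(0), contig_id = character(0),
               start = integer(0), end = integer(0),
               repeat_consensus = character(0), programs = character(0),
               acceptance_rule = character(0), cas_adjacent = logical(0),
               leader_end = character(0), complete = logical(0))
  repeats <- if (length(rows_r)) do.call(rbind, rows_r) else
    data.frame(cassette_id = character(0), contig_id = character(0),
               start = integer(0), end = integer(0))
  rownames(cassettes) <- rownames(repeats) <- NULL
  set <- list(cassettes = cassettes, repeats = repeats, spacers = NULL,
              rejected = candidates$candidate_id[is.na(rule)])
  extract_spacers(set, contigs)
}

#' Extract spacers from a cassette set
#'
#' Spacer intervals are the gaps between consecutive repeat copies. Serials
#' are provisional left-to-right until [orient_cassettes()] renumbers them
#' from the leader. Uniqueness is counted on the canonical
#' (strand-insensitive) sequence.
#'
#' @param cassette_set list with `cassettes` and `repeats`.
#' @param contigs contig table.
#' @return the cassette set with `spacers` filled and a `summary` element
#'   (total and unique spacer counts per dataset).
#' @export
extract_spacers <- function(cassette_set, contigs) {
  reps <- cassette_set$repeats
  rows <- list()
  drop <- character(0)
  for (cid in unique(reps$cassette_id)) {
    g <- reps[reps$cassette_id == cid, ]
    g <- g[order(g$start), ]
    if (nrow(g) < 2 || all(g$start[-1] == g$end[-nrow(g)])) {
      warning("cassette without spacers excluded: ", cid)
      drop <- c(drop, cid)
      next
    }
    s <- g$end[-nrow(g)]; e <- g$start[-1]
    keep <- e > s
    s <- s[keep]; e <- e[keep]
    seq <- contigs$sequence[match(g$contig_id[1], contigs$contig_id)]
    rows[[length(rows) + 1]] <- data.frame(
      cassette_id = cid, contig_id = g$contig_id[1],
      serial = seq_along(s), start = s, end = e,
      sequence = substring(seq, s + 1L, e),
      provisional = TRUE, stringsAsFactors = FALSE)
  }
  spacers <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cassette_id = character(0), contig_id = character(0),
               serial = integer(0), start = integer(0), end = integer(0),
               sequence = character(0), provisional = logical(0))
  spacers$canonical <- canonical_seq(spacers$sequence)
  rownames(spacers) <- NULL
  cassette_set$spacers <- spacers
  if (length(drop))
    cassette_set$cassettes <-
      cassette_set$cassettes[!(cassette_set$cassettes$cassette_id %in% drop), ]
  ds <- contigs$dataset[match(spacers$contig_id, contigs$contig_id)]
  cassette_set$summary <- do.call(rbind, lapply(split(spacers$canonical, ds),
    function(x) data.frame(total = length(x), unique = length(unique(x)))))
  cassette_set
}
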