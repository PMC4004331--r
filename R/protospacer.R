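# Spacer-protospacer matching: exhaustive full-length Hamming scanning (the
# default engine, which has no word-size edge artifacts), ingestion and
# full-length extension of external BLAST hits, the repeat-contamination
# filter, the pseudospacer randomized control, and PAM flank extraction.

# Internal matcher: all full-length windows of `target` within `max_mm`
# Hamming distance of `pattern`, on the given strand of the target.
# Candidate windows come from Biostrings::matchPattern; the mismatch count
# used for the threshold is recomputed here so that N never counts as a
# match on either side.
scan_one <- function(pattern, target_seq, max_mm) {
  L <- nchar(pattern)
  if (L > nchar(target_seq)) return(integer(0))
  n_in_pat <- sum(strsplit(pattern, "")[[1]] == "N")
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(target_seq),
                                max.mismatch = max_mm + n_in_pat,
                                with.indels = FALSE, fixed = TRUE)
  st <- Biostrings::start(m) - 1L # 0-based
  # matchPattern may report matches hanging over the subject ends when
  # mismatches are allowed; only full-length windows count here
  st <- st[st >= 0L & st + L <= nchar(target_seq)]
  if (!length(st)) return(integer(0))
  mm <- vapply(st, function(s)
    hamming_n(pattern, substr0(target_seq, s, s + L)), 0L)
  st[mm <= max_mm]
}

flanks_of <- function(target_seq, s, e, strand, width = 10L) {
  n <- nchar(target_seq)
  left <- substr0(target_seq, max(0L, s - width), s)
  right <- substr0(target_seq, e, min(n, e + width))
  if (strand == "+") c(left, right) else c(revcomp(right), revcomp(left))
}

overlaps_any <- function(s, e, iv_start, iv_end) {
  any(s < iv_end & iv_start < e)
}

#' Exhaustive spacer-protospacer scan
#'
#' Both-strand sliding-window ungapped Hamming comparison at full spacer
#' length; hits with at most `max_mismatches` mismatches are reported with
#' their 10-nt flanks (read 5'->3' on the hit strand). Windows overlapping
#' any cassette or candidate interval are excluded, as is each spacer's own
#' source locus. `N` counts as a mismatch on either side.
#'
#' @param spacers spacer table (`cassette_id`, `contig_id`, `serial`,
#'   `sequence`, `start`, `end`). A pseudospacer table works too.
#' @param targets contig table to scan.
#' @param exclude data.frame of intervals (`contig_id`, `start`, `end`) no
#'   hit may overlap - normally all cassette/candidate intervals.
#' @param max_mismatches reliability threshold (default 4).
#' @param flank_width flank length captured per side (default 10).
#' @return hit table: `spacer_key`, `cassette_id`, `serial`,
#'   `target_contig_id`, `start`, `end`, `strand`, `mismatches`,
#'   `flank_left`, `flank_right`, `source`, `passed_repeat_filter`.
#' @export
scan_targets <- function(spacers, targets, exclude = NULL,
                         max_mismatches = 4L, flank_width = 10L) {
  rows <- list()
  for (i in seq_len(nrow(spacers))) {
    sp <- spacers[i, ]
    pats <- c(`+` = sp$sequence, `-` = revcomp(sp$sequence))
    L <- nchar(sp$sequence)
    for (t in seq_len(nrow(targets))) {
      tg <- targets[t, ]
      excl <- if (is.null(exclude)) NULL else
        exclude[exclude$contig_id == tg$contig_id, , drop = FALSE]
      for (strand in c("+", "-")) {
        st <- scan_one(pats[[strand]], tg$sequence, max_mismatches)
        for (s in st) {
          e <- s + L
          if (!is.null(excl) && nrow(excl) &&
              overlaps_any(s, e, excl$start, excl$end)) next
          if (tg$contig_id == sp$contig_id &&
              overlaps_any(s, e, sp$start, sp$end)) next
          fl <- flanks_of(tg$sequence, s, e, strand, flank_width)
          rows[[length(rows) + 1]] <- data.frame(
            spacer_key = paste(sp$cassette_id, sp$serial, sep = ":"),
            cassette_id = sp$cassette_id, serial = sp$serial,
            target_contig_id = tg$contig_id, start = s, end = e,
            strand = strand,
            mismatches = hamming_n(pats[[strand]],
                                   substr0(tg$sequence, s, e)),
            flank_left = fl[1], flank_right = fl[2],
            source = "internal_scan", passed_repeat_filter = NA,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(spacer_key = character(0), cassette_id = character(0),
               serial = integer(0), target_contig_id = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               mismatches = integer(0), flank_left = character(0),
               flank_right = character(0), source = character(0),
               passed_repeat_filter = logical(0))
  # dedupe by (spacer, target, interval, strand); opposite-strand overlaps
  # of the same spacer are distinct hits and both kept
  key <- paste(out$spacer_key, out$target_contig_id, out$start, out$end,
               out$strand)
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extend a raw BLAST hit to full spacer length
#'
#' Word-based aligners truncate alignments whose mismatches sit within one
#' word of an end; the hit is therefore widened (strand-aware) so the
#' subject interval corresponds to spacer positions 1..L, and the mismatch
#' count is recomputed by ungapped Hamming comparison over the full length.
#' Gapped raw hits are rejected (the mismatch threshold is an ungapped
#' notion), as are hits whose extension would run past a contig end.
#'
#' @param raw one row from [ingest_blast_tab()]; `query` must name a spacer
#'   and `subject` a target contig.
#' @param spacers spacer table with `spacer_key` = `cassette_id:serial` keys
#'   (built if missing).
#' @param targets contig table.
#' @param max_mismatches reliability threshold (default 4; hits above it are
#'   returned with `reliable = FALSE` semantics, i.e. dropped).
#' @param flank_width flank length (default 10).
#' @return a one-row hit table (`source = "blast_extended"`), or a
#'   `blast_rejection` object whose `reason` element is one of `"gapped"`,
#'   `"contig_end"`, `"mismatch_threshold"`.
#' @export
extend_blast_hit <- function(raw, spacers, targets, max_mismatches = 4L,
                             flank_width = 10L) {
  if (is.null(spacers$spacer_key))
    spacers$spacer_key <- paste(spacers$cassette_id, spacers$serial, sep = ":")
  reject <- function(reason)
    structure(list(reason = reason), class = "blast_rejection")
  si <- match(raw$query, spacers$spacer_key)
  ti <- match(raw$subject, targets$contig_id)
  if (is.na(si)) stop("unknown spacer id in BLAST hit: ", raw$query)
  if (is.na(ti)) stop("unknown target contig in BLAST hit: ", raw$subject)
  if (isTRUE(raw$gapped)) return(reject("gapped"))
  sp <- spacers[si, ]; tg <- targets[ti, ]
  L <- nchar(sp$sequence)
  qs <- raw$qstart; qe <- raw$qend
  if (raw$strand == "+") {
    s0 <- raw$sstart - (qs - 1L)
    e0 <- raw$send + (L - qe)
  } else {
    s0 <- raw$sstart - (L - qe)
    e0 <- raw$send + (qs - 1L)
  }
  if (s0 < 0 || e0 > tg$length) return(reject("contig_end"))
  window <- substr0(tg$sequence, s0, e0)
  proto <- if (raw$strand == "+") window else revcomp(window)
  mm <- hamming_n(sp$sequence, proto)
  if (mm > max_mismatches) return(reject("mismatch_threshold"))
  fl <- flanks_of(tg$sequence, s0, e0, raw$strand, flank_width)
  data.frame(
    spacer_key = sp$spacer_key, cassette_id = sp$cassette_id,
    serial = sp$serial, target_contig_id = tg$contig_id,
    start = s0, end = e0, strand = raw$strand, mismatches = mm,
    flank_left = fl[1], flank_right = fl[2], source = "blast_extended",
    passed_repeat_filter = NA, stringsAsFactors = FALSE)
}

# mismatch budget used for contamination scans: no threshold is standard for
# this, so it scales with query length (~15%, the 4-of-27 spacer ratio)
contamination_budget <- function(len, rate = 0.15) as.integer(ceiling(rate * len))

#' Repeat-contamination filter
#'
#' A spacer hit in a contig that also matches the repeat of the spacer's own
#' cassette is probably an undetected CRISPR array, not a protospacer. For
#' every hit, the repeat consensus of the spacer's cassette is scanned (both
#' strands, mismatch budget `ceiling(0.15 * repeat length)`) against the
#' hit's target contig; a repeat match on the same contig fails the hit.
#' Only hits with `passed_repeat_filter == TRUE` are "reliable".
#'
#' @param hits hit table from [scan_targets()] / [extend_blast_hit()].
#' @param cassettes cassette table (`cassette_id`, `repeat_consensus`).
#' @param targets contig table.
#' @return the hit table with `passed_repeat_filter` set.
#' @export
repeat_contamination_filter <- function(hits, cassettes, targets) {
  if (!nrow(hits)) return(hits)
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(hits))) {
    rep_seq <- cassettes$repeat_consensus[
      match(hits$cassette_id[i], cassettes$cassette_id)]
    key <- paste(hits$cassette_id[i], hits$target_contig_id[i])
    if (!is.null(cache[[key]])) {
      hits$passed_repeat_filter[i] <- cache[[key]]
      next
    }
    tg <- targets$sequence[match(hits$target_contig_id[i], targets$contig_id)]
    budget <- contamination_budget(nchar(rep_seq))
    found <- length(scan_one(rep_seq, tg, budget)) > 0 ||
      length(scan_one(revcomp(rep_seq), tg, budget)) > 0
    cache[[key]] <- !found
    hits$passed_repeat_filter[i] <- !found
  }
  hits
}

#' Reliable hits
#'
#' Convenience filter: full-length hits with at most `max_mismatches`
#' mismatches that passed the repeat-contamination filter.
#'
#' @param hits hit table.
#' @param max_mismatches threshold (default 4).
#' @return filtered hit table.
#' @export
reliable_hits <- function(hits, max_mismatches = 4L) {
  hits[hits$mismatches <= max_mismatches &
         (is.na(hits$passed_repeat_filter) | hits$passed_repeat_filter) &
         !is.na(hits$spacer_key), , drop = FALSE]
}

#' Build the pseudospacer randomized control
#'
#' Each spacer is replaced by a random fragment of the same length drawn
#' uniformly from the positions of its source contig that lie outside every
#' cassette interval. When both non-cassette flanks of the source cassette
#' are shorter than 100 nt, the fragment is taken from a randomly selected
#' cassette-free contig of the same individual instead; if none exists the
#' pseudospacer is skipped with a warning.
#'
#' @param spacers spacer table.
#' @param contigs contig table.
#' @param cassette_intervals data.frame `contig_id`, `start`, `end` of all
#'   cassette (and candidate) intervals.
#' @param seed RNG seed: fixed seed, identical pseudospacers.
#' @param min_flank the 100-nt flank rule (default 100).
#' @return pseudospacer table in the spacer schema, plus a `rule` column
#'   recording which randomization rule fired.
#' @export
make_pseudospacers <- function(spacers, contigs, cassette_intervals,
                               seed = 1L, min_flank = 100L) {
  set.seed(seed)
  has_cassette <- unique(cassette_intervals$contig_id)
  rows <- list()
  for (i in seq_len(nrow(spacers))) {
    sp <- spacers[i, ]
    L <- nchar(sp$sequence)
    src <- contigs[match(sp$contig_id, contigs$contig_id), ]
    iv <- cassette_intervals[cassette_intervals$contig_id == sp$contig_id, ,
                             drop = FALSE]
    cass_s <- min(iv$start); cass_e <- max(iv$end)
    use_fallback <- (cass_s < min_flank) &&
      (src$length - cass_e < min_flank)
    if (!use_fallback) {
      starts <- 0:(src$length - L)
      ok <- !vapply(starts, function(s)
        overlaps_any(s, s + L, iv$start, iv$end), TRUE)
      starts <- starts[ok]
      if (!length(starts)) use_fallback <- TRUE
    }
    if (!use_fallback) {
      s <- if (length(starts) == 1) starts else sample(starts, 1)
      rows[[length(rows) + 1]] <- data.frame(
        cassette_id = sp$cassette_id, contig_id = sp$contig_id,
        serial = sp$serial, start = s, end = s + L,
        sequence = substr0(src$sequence, s, s + L), rule = "same_contig",
        stringsAsFactors = FALSE)
      next
    }
    pool <- contigs[contigs$individual_id == src$individual_id &
                      !(contigs$contig_id %in% has_cassette) &
                      contigs$length >= L, , drop = FALSE]
    if (!nrow(pool)) {
      warning("no cassette-free contig for pseudospacer of ",
              sp$cassette_id, ":", sp$serial, "; skipped")
      next
    }
    j <- if (nrow(pool) == 1) 1L else sample(nrow(pool), 1)
    s <- floor(stats::runif(1) * (pool$length[j] - L + 1L))
    rows[[length(rows) + 1]] <- data.frame(
      cassette_id = sp$cassette_id, contig_id = pool$contig_id[j],
      serial = sp$serial, start = s, end = s + L,
      sequence = substr0(pool$sequence[j], s, s + L),
      rule = "fallback_contig", stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cassette_id = character(0), contig_id = character(0),
               serial = integer(0), start = integer(0), end = integer(0),
               sequence = character(0), rule = character(0))
  rownames(out) <- NULL
  out
}

#' Homology filter on pseudospacer flanks
#'
#' Gene homology would make a pseudospacer and its flanks match the same
#' target; such pairs say nothing about CRISPR targeting. For each
#' pseudospacer hit, both flanks of the pseudospacer - with the length of
#' the repeats of the respective cassette - are scanned against the pair's
#' target contig (same mismatch-budget policy as the repeat filter); any
#' flank match discards the pair. A flank truncated by a contig end is used
#' when at least half the repeat length remains and treated as non-matching
#' otherwise.
#'
#' @param pseudo_hits hits of pseudospacers from [scan_targets()].
#' @param pseudospacers the pseudospacer table (for flank coordinates).
#' @param cassettes cassette table (repeat lengths per cassette).
#' @param contigs contig table (pseudospacer source sequences).
#' @param targets contig table scanned (usually the same).
#' @return the surviving pseudo hit rows.
#' @export
pseudo_flank_filter <- function(pseudo_hits, pseudospacers, cassettes,
                                contigs, targets = contigs) {
  if (!nrow(pseudo_hits)) return(pseudo_hits)
  keep <- rep(TRUE, nrow(pseudo_hits))
  for (i in seq_len(nrow(pseudo_hits))) {
    h <- pseudo_hits[i, ]
    ps <- pseudospacers[paste(pseudospacers$cassette_id, pseudospacers$serial,
                              sep = ":") == h$spacer_key, ][1, ]
    rep_len <- nchar(cassettes$repeat_consensus[
      match(h$cassette_id, cassettes$cassette_id)])
    src <- contigs[match(ps$contig_id, contigs$contig_id), ]
    tg <- targets$sequence[match(h$target_contig_id, targets$contig_id)]
    budget <- contamination_budget(rep_len)
    fl_left <- substr0(src$sequence, max(0L, ps$start - rep_len), ps$start)
    fl_right <- substr0(src$sequence, ps$end,
                        min(src$length, ps$end + rep_len))
    for (fl in c(fl_left, fl_right)) {
      if (nchar(fl) < ceiling(rep_len / 2)) next # truncated: non-matching
      if (length(scan_one(fl, tg, budget)) > 0 ||
          length(scan_one(revcomp(fl), tg, budget)) > 0) {
        keep[i] <- FALSE
        break
      }
    }
  }
  pseudo_hits[keep, , drop = FALSE]
}

#' Per-group PAM flank table
#'
#' @param hits reliable hit table.
#' @param clusters repeat clustering of the hits' cassettes (used as PAM
#'   grouping); a data.frame `cassette_id`, `cluster_id`.
#' @return the hits with a `group` column (repeat cluster of the spacer's
#'   cassette).
#' @export
extract_pam_flanks <- function(hits, clusters) {
  hits$group <- clusters$cluster_id[match(hits$cassette_id,
                                          clusters$cassette_id)]
  hits[c("spacer_key", "group", "strand", "flank_left", "flank_right")]
}

ic_profile <- function(flanks, width, align = c("right", "left")) {
  align <- match.arg(align)
  mat <- matrix(NA_character_, nrow = length(flanks), ncol = width)
  for (i in seq_along(flanks)) {
    ch <- strsplit(flanks[i], "")[[1]]
    if (!length(ch)) next
    if (align == "right")
      mat[i, (width - length(ch) + 1L):width] <- ch
    else mat[i, seq_along(ch)] <- ch
  }
  apply(mat, 2, function(col) {
    col <- col[!is.na(col) & col != "N"]
    if (length(col) == 0) return(NA_real_)
    p <- table(factor(col, levels = c("A", "C", "G", "T"))) / length(col)
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

#' Scan grouped protospacer flanks for a PAM motif
#'
#' Per group (repeat cluster) and side, position-wise base frequencies and
#' information content (2 - entropy, bits) are computed over the up-to-10-nt
#' flanks; left flanks are aligned on the protospacer-proximal end. A motif
#' is reported only when at least `min_run` consecutive positions each reach
#' `min_bits`; groups with fewer than `min_hits` protospacers are skipped.
#'
#' @param pam_flanks output of [extract_pam_flanks()].
#' @param min_hits minimum protospacers per group (default 3).
#' @param min_bits information-content threshold per position (default 1.0).
#' @param min_run consecutive qualifying positions required (default 2).
#' @param flank_width flank width used at extraction (default 10).
#' @return data.frame per group and side: `group`, `side`, `n`, `max_ic`,
#'   `motif` (`NA` when no reliable PAM).
#' @export
pam_scan <- function(pam_flanks, min_hits = 3L, min_bits = 1.0, min_run = 2L,
                     flank_width = 10L) {
  out <- list()
  for (g in unique(pam_flanks$group)) {
    gf <- pam_flanks[pam_flanks$group == g, ]
    if (nrow(gf) < min_hits) next
    for (side in c("left", "right")) {
      flanks <- if (side == "left") gf$flank_left else gf$flank_right
      align <- if (side == "left") "right" else "left"
      ic <- ic_profile(flanks, flank_width, align)
      ok <- !is.na(ic) & ic >= min_bits
      runs <- rle(ok)
      motif <- NA_character_
      if (any(runs$values & runs$lengths >= min_run)) {
        ends <- cumsum(runs$lengths)
        ri <- which(runs$values & runs$lengths >= min_run)[1]
        idx <- (ends[ri] - runs$lengths[ri] + 1L):ends[ri]
        cons <- vapply(idx, function(j) {
          col <- vapply(flanks, function(f) {
            ch <- strsplit(f, "")[[1]]
            w <- flank_width
            padded <- rep(NA_character_, w)
            if (length(ch)) {
              if (align == "right") padded[(w - length(ch) + 1L):w] <- ch
              else padded[seq_along(ch)] <- ch
            }
            padded[j]
          }, "")
          col <- col[!is.na(col)]
          names(which.max(table(col)))
        }, "")
        motif <- paste(cons, collapse = "")
      }
      out[[length(out) + 1]] <- data.frame(
        group = g, side = side, n = nrow(gf),
        max_ic = suppressWarnings(max(ic, na.rm = TRUE)), motif = motif,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(group = character(0), side = character(0),
                      n = integer(0), max_ic = numeric(0),
                      motif = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
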