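# Repeat consensus, BLASTCLUST-style clustering of consensus repeats,
# cassette orientation from cas genes with cluster propagation, and cas-type
# assignment from locus composition.

#' Majority-vote consensus of repeat copies
#'
#' Copies of the modal length are column-wise majority voted; ties are broken
#' alphabetically (A < C < G < T). Copies of other lengths are ignored for
#' voting. If no length occurs twice, the first copy is returned verbatim
#' with a warning.
#'
#' @param copies character vector of repeat copies (>= 2).
#' @return consensus DNA string.
#' @export
consensus_repeat <- function(copies) {
  if (length(copies) < 2) stop("need at least 2 repeat copies")
  lens <- nchar(copies)
  tab <- table(lens)
  if (max(tab) < 2) {
    warning("no two repeat copies share a length; using first copy verbatim")
    return(copies[1])
  }
  modal <- as.integer(names(tab)[which.max(tab)])
  grp <- copies[lens == modal]
  m <- do.call(rbind, strsplit(grp, ""))
  cons <- apply(m, 2, function(col) {
    cnt <- table(factor(col, levels = c("A", "C", "G", "T", "N")))
    names(cnt)[which.max(cnt)] # which.max takes the first = alphabetical tie
  })
  paste(cons, collapse = "")
}

# Maximal-scoring ungapped extension of a seed on one diagonal.
# match = +1, mismatch = -2; returns span (alignment columns) and identity.
extend_seed_segment <- function(match_vec, seed_lo, seed_hi) {
  sc <- ifelse(match_vec, 1, -2)
  n <- length(sc)
  lo <- seed_lo; hi <- seed_hi
  if (seed_lo > 1) {
    cum <- rev(cumsum(rev(sc[1:(seed_lo - 1)])))
    best <- which.max(cum)
    if (cum[best] > 0) lo <- best
  }
  if (seed_hi < n) {
    cum <- cumsum(sc[(seed_hi + 1):n])
    best <- which.max(cum)
    if (cum[best] > 0) hi <- seed_hi + best
  }
  span <- hi - lo + 1L
  list(span = span, identity = sum(match_vec[lo:hi]) / span)
}

# Seeded, strand-aware link test between two repeat consensi.
repeat_link <- function(a, b, min_identity = 0.5, min_coverage = 0.5,
                        word_size = 15L) {
  params <- list(min_identity = min_identity, min_coverage = min_coverage,
                 word_size = word_size)
  repeat_link_one_strand(a, b, params) ||
    repeat_link_one_strand(a, revcomp(b), params)
}

#' Cluster consensus repeats (BLASTCLUST-style)
#'
#' Two repeats are linked when a word-seeded, ungapped local alignment
#' (exact shared word of `word_size` on either strand, extended to the
#' maximal-scoring segment under +1 match / -2 mismatch) reaches
#' `min_identity` over a span covering at least `min_coverage` of the longer
#' sequence. Clusters are connected components (single linkage), numbered by
#' their smallest member id, so the partition does not depend on input
#' order.
#'
#' @param consensi named character vector (names are cassette ids).
#' @param min_identity minimum identity fraction on the aligned span
#'   (default 0.50).
#' @param min_coverage minimum fraction of the longer sequence covered
#'   (default 0.50).
#' @param word_size exact seed word length (default 15).
#' @return data.frame `cassette_id`, `cluster_id` with the parameters as an
#'   attribute.
#' @export
cluster_repeats <- function(consensi, min_identity = 0.5, min_coverage = 0.5,
                            word_size = 15L) {
  if (is.null(names(consensi))) names(consensi) <- seq_along(consensi)
  ids <- names(consensi)
  n <- length(consensi)
  parent <- seq_len(n)
  find2 <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      ri <- find2(i); rj <- find2(j)
      if (ri == rj) next
      if (repeat_link(consensi[i], consensi[j], min_identity, min_coverage,
                      word_size))
        parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find2, 0L)
  # deterministic ordering: clusters numbered by the smallest member id
  rep_id <- vapply(split(ids, roots), function(x) min(x), "")
  ord <- order(rep_id)
  cl_num <- setNames(seq_along(ord), names(rep_id)[ord])
  out <- data.frame(cassette_id = ids,
                    cluster_id = sprintf("RC%03d", cl_num[as.character(roots)]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "params") <- list(min_identity = min_identity,
                              min_coverage = min_coverage,
                              word_size = word_size)
  out
}

# strand relation between two linked consensi: "+" if linked as-is, "-" if
# linked against the reverse complement, NA if neither.
repeat_strand_relation <- function(a, b, params) {
  plus <- repeat_link_one_strand(a, b, params)
  minus <- repeat_link_one_strand(a, revcomp(b), params)
  if (plus && !minus) return("+")
  if (minus && !plus) return("-")
  if (plus && minus) return("+") # palindromic-ish; treat as same strand
  NA_character_
}

repeat_link_one_strand <- function(a, bb, params) {
  la <- nchar(a); lb <- nchar(bb)
  w <- params$word_size
  if (la < w || lb < w) return(FALSE)
  ra <- strsplit(a, "")[[1]]; rb <- strsplit(bb, "")[[1]]
  pa <- seq_len(la - w + 1L); ka <- substring(a, pa, pa + w - 1L)
  pb <- seq_len(lb - w + 1L); kb <- substring(bb, pb, pb + w - 1L)
  common <- setdiff(intersect(ka, kb), grep("N", intersect(ka, kb), value = TRUE))
  if (!length(common)) return(FALSE)
  longer <- max(la, lb)
  diags <- unique(unlist(lapply(common, function(wd)
    outer(pa[ka == wd], pb[kb == wd], `-`))))
  for (d in diags) {
    i1 <- max(1L, 1L + d); i2 <- min(la, lb + d)
    if (i2 < i1) next
    mv <- ra[i1:i2] == rb[(i1:i2) - d] & ra[i1:i2] != "N"
    seed_start <- NA_integer_
    for (wd in common) {
      for (s in pa[ka == wd]) if ((s - d) %in% pb[kb == wd]) {
        seed_start <- s; break
      }
      if (!is.na(seed_start)) break
    }
    if (is.na(seed_start)) next
    lo <- seed_start - i1 + 1L
    seg <- extend_seed_segment(mv, lo, lo + w - 1L)
    if (seg$identity >= params$min_identity &&
        seg$span / longer >= params$min_coverage) return(TRUE)
  }
  FALSE
}

#' Orient cassettes and renumber spacers from the leader
#'
#' Stage 1: a cassette with a cas gene within the adjacency window gets its
#' leader at the cassette end nearer the cas locus (with `strict = TRUE` the
#' gene must additionally be transcribed toward the cassette). Stage 2:
#' unoriented cassettes inherit orientation from oriented members of their
#' repeat cluster, matching repeat strand (consensus vs reverse-complement
#' consensus) under the assumption that the repeat is encoded on the same
#' strand throughout a cluster. Conflicting evidence leaves `leader_end`
#' unknown. Spacers of oriented cassettes are renumbered from the leader
#' (`serial = n + 1 - left_serial` when the leader is on the right); the
#' operation is idempotent.
#'
#' @param cassette_set cassette set from [consensus_filter()].
#' @param cas cas gene annotations.
#' @param clusters output of [cluster_repeats()] on these cassettes.
#' @param adjacency_window nt window for cas adjacency (default 2000).
#' @param strict require cas transcription toward the cassette (default
#'   FALSE; the weakest defensible reading of leader-side evidence).
#' @return the cassette set with `leader_end` set and spacers renumbered.
#' @export
orient_cassettes <- function(cassette_set, cas, clusters,
                             adjacency_window = 2000L, strict = FALSE) {
  cs <- cassette_set$cassettes
  params <- attr(clusters, "params") %||%
    list(min_identity = 0.5, min_coverage = 0.5, word_size = 15L)
  leader <- rep("unknown", nrow(cs))
  # stage 1: cas evidence
  for (i in seq_len(nrow(cs))) {
    idx <- which(cas$contig_id == cs$contig_id[i])
    if (!length(idx)) next
    g <- cas[idx, , drop = FALSE]
    gap <- pmax(g$start - cs$end[i], cs$start[i] - g$end, 0L)
    g <- g[gap <= adjacency_window, , drop = FALSE]
    if (!nrow(g)) next
    mid <- (g$start + g$end) / 2
    d_left <- abs(mid - cs$start[i]); d_right <- abs(mid - cs$end[i])
    side <- ifelse(d_left <= d_right, "left", "right")
    if (strict) {
      toward <- (side == "left" & g$strand == "+") |
        (side == "right" & g$strand == "-")
      g <- g[toward, , drop = FALSE]; side <- side[toward]
      if (!nrow(g)) next
    }
    nearest <- which.min(pmin(abs(mid - cs$start[i]), abs(mid - cs$end[i]))[
      seq_len(nrow(g))])
    leader[i] <- side[nearest]
  }
  # stage 2: propagate within repeat clusters by repeat strand
  cl <- clusters$cluster_id[match(cs$cassette_id, clusters$cassette_id)]
  for (k in unique(cl)) {
    idx <- which(cl == k)
    anchors <- idx[leader[idx] != "unknown"]
    floating <- idx[leader[idx] == "unknown"]
    if (!length(anchors) || !length(floating)) next
    for (f in floating) {
      implied <- character(0)
      for (a in anchors) {
        rel <- repeat_strand_relation(cs$repeat_consensus[a],
                                      cs$repeat_consensus[f], params)
        if (is.na(rel)) next
        implied <- c(implied,
                     if (rel == "+") leader[a]
                     else if (leader[a] == "left") "right" else "left")
      }
      implied <- unique(implied)
      if (length(implied) == 1) leader[f] <- implied
      else if (length(implied) > 1)
        message("conflicting cluster orientation for ", cs$cassette_id[f],
                "; left unknown")
    }
  }
  cs$leader_end <- leader
  cassette_set$cassettes <- cs
  sp <- cassette_set$spacers
  if (!is.null(sp) && nrow(sp)) {
    sp <- sp[order(sp$cassette_id, sp$start), ]
    for (i in seq_len(nrow(cs))) {
      m <- sp$cassette_id == cs$cassette_id[i]
      if (!any(m)) next
      n <- sum(m)
      left_serial <- seq_len(n) # spacers are coordinate-sorted
      if (cs$leader_end[i] == "right") {
        sp$serial[m] <- n + 1L - left_serial
        sp$provisional[m] <- FALSE
      } else if (cs$leader_end[i] == "left") {
        sp$serial[m] <- left_serial
        sp$provisional[m] <- FALSE
      } else {
        sp$serial[m] <- left_serial
        sp$provisional[m] <- TRUE
      }
    }
    rownames(sp) <- NULL
    cassette_set$spacers <- sp
  }
  cassette_set
}

#' Assign a CRISPR-cas system type from adjacent cas genes
#'
#' Signature mapping (configurable): cas3 marks type I, cas9 type II, cas10
#' type III. Loci with only universal genes (cas1/cas2) stay unclassified;
#' conflicting signatures stay unclassified with all evidence listed.
#'
#' @param genes character vector of cas gene names near one cassette.
#' @param signatures named character vector mapping signature gene to type.
#' @return list `type` (`"I"`, `"II"`, `"III"` or `"unclassified"`) and
#'   `evidence` (genes used).
#' @export
assign_cas_type <- function(genes,
                            signatures = c(cas3 = "I", cas9 = "II",
                                           cas10 = "III")) {
  genes <- tolower(genes)
  sig <- genes[genes %in% names(signatures)]
  types <- unique(unname(signatures[sig]))
  if (length(types) == 1) list(type = types, evidence = unique(sig))
  else if (length(types) > 1) list(type = "unclassified", evidence = unique(sig))
  else list(type = "unclassified", evidence = character(0))
}
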