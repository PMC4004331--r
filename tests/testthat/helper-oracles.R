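# Independent oracles used across the suite. These deliberately share no
# code with the package implementations they check.

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_k <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

rc_str <- function(x) {
  unname(chartr("ACGTN", "TGCAN",
                vapply(x, function(s)
                  paste(rev(strsplit(s, "")[[1]]), collapse = ""), "")))
}

# mismatch count of `pat` against every full-length window of `tgt`
# (N is a mismatch on either side); vector indexed by 0-based window start + 1
oracle_mm_profile <- function(pat, tgt) {
  L <- nchar(pat); n <- nchar(tgt)
  if (L > n) return(integer(0))
  tr <- charToRaw(tgt); pr <- charToRaw(pat); NN <- charToRaw("N")
  mm <- integer(n - L + 1)
  for (j in seq_len(L)) {
    a <- tr[j:(j + n - L)]
    mm <- mm + as.integer(a != pr[j] | a == NN | pr[j] == NN)
  }
  mm
}

# naive both-strand full-length scan: data.frame(start, strand, mismatches)
oracle_scan <- function(spacer, target, max_mm = 4L) {
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") spacer else rc_str(spacer)
    mm <- oracle_mm_profile(pat, target)
    hit <- which(mm <= max_mm)
    if (length(hit))
      out[[strand]] <- data.frame(start = hit - 1L, strand = strand,
                                  mismatches = mm[hit])
  }
  if (!length(out))
    return(data.frame(start = integer(0), strand = character(0),
                      mismatches = integer(0)))
  do.call(rbind, out)
}

# Unseeded ungapped local-alignment link oracle (+1 match / -2 mismatch):
# over every diagonal on both strands, every maximal positive-scoring
# segment is tested for identity >= min_id over a span covering
# >= min_cov of the longer sequence.
oracle_repeat_link <- function(a, b, min_id = 0.5, min_cov = 0.5) {
  la <- nchar(a); lb <- nchar(b); longer <- max(la, lb)
  ra <- strsplit(a, "")[[1]]
  for (bb in c(b, rc_str(b))) {
    rb <- strsplit(bb, "")[[1]]
    for (d in (1 - lb):(la - 1)) {
      i1 <- max(1L, 1L + d); i2 <- min(la, lb + d)
      if (i2 < i1) next
      mv <- ra[i1:i2] == rb[(i1:i2) - d] & ra[i1:i2] != "N"
      sc <- ifelse(mv, 1, -2)
      # Kadane decomposition: best segment inside every positive stretch
      cur <- 0; cur_start <- 1L
      best <- -Inf; b1 <- b2 <- 0L
      flush <- function() {
        if (best > 0) {
          span <- b2 - b1 + 1L
          if (sum(mv[b1:b2]) / span >= min_id && span / longer >= min_cov)
            return(TRUE)
        }
        FALSE
      }
      for (i in seq_along(sc)) {
        if (cur <= 0) { cur <- 0; cur_start <- i }
        cur <- cur + sc[i]
        if (cur > best) { best <- cur; b1 <- cur_start; b2 <- i }
        if (cur <= 0) { if (flush()) return(TRUE); best <- -Inf }
      }
      if (flush()) return(TRUE)
    }
  }
  FALSE
}

# tiny synthetic community reused by several files
small_community <- function(seed = 11, ...) {
  cfg <- simulation_config(
    n_individuals = 3, contigs_per_individual = 3,
    contig_length_range = c(2500, 4000), n_cassettes = 6,
    spacers_per_cassette_range = c(5, 8), n_phage_contigs = 3,
    n_protospacers = 12, seed = seed, ...)
  generate_community(cfg)
}
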