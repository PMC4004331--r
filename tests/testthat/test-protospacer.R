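spacer_row <- function(seq, cassette = "k1", serial = 1L, contig = "src",
                       start = 0L) {
  data.frame(cassette_id = cassette, contig_id = contig, serial = serial,
             start = start, end = start + nchar(seq), sequence = seq,
             provisional = FALSE, canonical = canonical_seq(seq),
             stringsAsFactors = FALSE)
}

target_row <- function(id, seq, ind = "indA") {
  data.frame(contig_id = id, individual_id = ind, dataset = "SYN",
             sequence = seq, length = nchar(seq), stringsAsFactors = FALSE)
}

test_that("the scan reports planted hits at the 4-mismatch threshold and not
           beyond", {
  set.seed(61)
  sp <- random_dna_str(30)
  at4 <- mutate_k(sp, 4); at5 <- mutate_k(sp, 5)
  tgt <- paste0(random_dna_str(300), at4, random_dna_str(200), at5,
                random_dna_str(300))
  hits <- scan_targets(spacer_row(sp), target_row("t1", tgt))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 300L)
  expect_equal(hits$mismatches, 4L)
  expect_equal(nchar(hits$flank_left), 10L)
  # minus-strand planting is found with strand-aware flanks
  rc_at2 <- rc_str(mutate_k(sp, 2))
  tgt2 <- paste0(random_dna_str(100), rc_at2, random_dna_str(100))
  h2 <- scan_targets(spacer_row(sp), target_row("t2", tgt2))
  expect_equal(h2$strand, "-")
  expect_equal(h2$mismatches, 2L)
  # the 5' flank on the hit strand is the reverse complement of the
  # downstream plus-strand context
  expect_equal(h2$flank_left,
               rc_str(substr(tgt2, 100 + 30 + 1, 100 + 30 + 10)))
})

test_that("a spacer never hits its own locus or any cassette interval", {
  set.seed(62)
  sp <- random_dna_str(32)
  contig <- paste0(random_dna_str(150), sp, random_dna_str(150))
  spacers <- spacer_row(sp, contig = "c1", start = 150L)
  targets <- target_row("c1", contig)
  expect_equal(nrow(scan_targets(spacers, targets)), 0L)
  # an identical copy elsewhere is masked when covered by a cassette interval
  contig2 <- paste0(random_dna_str(100), sp, random_dna_str(100))
  t2 <- target_row("c2", contig2)
  excl <- data.frame(contig_id = "c2", start = 90L, end = 140L)
  expect_equal(nrow(scan_targets(spacers, t2, exclude = excl)), 0L)
  expect_equal(nrow(scan_targets(spacers, t2)), 1L)
})

test_that("the scan matches the brute-force oracle on random instances", {
  set.seed(63)
  for (case in 1:60) {
    L <- sample(25:45, 1)
    sp <- random_dna_str(L)
    tgt <- random_dna_str(sample(200:500, 1))
    # plant something nearby half the time so hits actually occur
    if (case %% 2 == 0) {
      h <- sample(0:5, 1)
      ins <- if (runif(1) < 0.5) mutate_k(sp, h) else rc_str(mutate_k(sp, h))
      pos <- sample(0:(nchar(tgt) - L), 1)
      tgt <- paste0(substr(tgt, 1, pos), ins, substr(tgt, pos + L + 1,
                                                     nchar(tgt)))
    }
    got <- scan_targets(spacer_row(sp), target_row("t", tgt))
    want <- oracle_scan(sp, tgt)
    got <- got[order(got$start, got$strand), ]
    want <- want[order(want$start, want$strand), ]
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$mismatches, want$mismatches)
  }
})

test_that("N counts as a mismatch on both sides", {
  sp <- "ACGTACGTACGTACGTACGTACGTA"
  tgt_n <- sub("^ACGT", "NCGT", sp)
  h <- scan_targets(spacer_row(sp), target_row("t", paste0(tgt_n,
                                                           strrep("G", 50))))
  expect_equal(h$mismatches[h$start == 0], 1L)
  spn <- sub("^ACGT", "NCGT", sp)
  h2 <- scan_targets(spacer_row(spn), target_row("t", paste0(spn,
                                                             strrep("G", 50))))
  expect_equal(h2$mismatches[h2$start == 0], 1L) # N vs N is still a mismatch
})

test_that("BLAST hits are extended to full spacer length with recomputed
           mismatches", {
  set.seed(64)
  sp <- random_dna_str(30)
  spacers <- spacer_row(sp)
  spacers$spacer_key <- "k1:1"
  # identity extension: alignment covers spacer positions 3..30
  tgt <- paste0(random_dna_str(50), sp, random_dna_str(50))
  targets <- target_row("t1", tgt)
  raw <- data.frame(query = "k1:1", subject = "t1", qstart = 3, qend = 30,
                    sstart = 52L, send = 80L, strand = "+", gapped = FALSE)
  h <- extend_blast_hit(raw, spacers, targets)
  expect_equal(h$start, 50L); expect_equal(h$end, 80L)
  expect_equal(h$mismatches, 0L)
  # a mismatch revealed at spacer position 1 by the extension is counted
  tgt2 <- tgt
  substr(tgt2, 51, 51) <- setdiff(c("A", "C", "G", "T"),
                                  substr(sp, 1, 1))[1]
  h2 <- extend_blast_hit(raw, spacers, target_row("t1", tgt2))
  expect_equal(h2$mismatches, 1L)
  # minus-strand extension lands on the planted interval
  tgt3 <- paste0(random_dna_str(40), rc_str(sp), random_dna_str(40))
  raw3 <- data.frame(query = "k1:1", subject = "t3", qstart = 3, qend = 28,
                     sstart = 42L, send = 68L, strand = "-", gapped = FALSE)
  h3 <- extend_blast_hit(raw3, spacers, target_row("t3", tgt3))
  expect_equal(h3$start, 40L); expect_equal(h3$end, 70L)
  expect_equal(h3$mismatches, 0L)
  # extension past the contig start is rejected, as are gapped hits
  raw4 <- data.frame(query = "k1:1", subject = "t4", qstart = 3, qend = 30,
                     sstart = 1L, send = 29L, strand = "+", gapped = FALSE)
  near_end <- target_row("t4", paste0(substr(sp, 3, 30), random_dna_str(60)))
  r4 <- extend_blast_hit(raw4, spacers, near_end)
  expect_s3_class(r4, "blast_rejection")
  expect_equal(r4$reason, "contig_end")
  raw5 <- raw; raw5$gapped <- TRUE
  r5 <- extend_blast_hit(raw5, spacers, targets)
  expect_s3_class(r5, "blast_rejection")
  expect_equal(r5$reason, "gapped")
})

test_that("extension mismatch counts equal the direct Hamming oracle", {
  set.seed(65)
  for (case in 1:60) {
    L <- sample(25:40, 1)
    sp <- random_dna_str(L)
    h_true <- sample(0:4, 1)
    proto <- mutate_k(sp, h_true)
    strand <- sample(c("+", "-"), 1)
    pos <- sample(20:60, 1)
    ins <- if (strand == "+") proto else rc_str(proto)
    tgt <- paste0(random_dna_str(pos), ins, random_dna_str(40))
    qs <- sample(1:5, 1); qe <- L - sample(0:4, 1)
    # normalized subject interval (0-based half-open, plus strand) of the
    # aligned query range [qs, qe]
    if (strand == "+") {
      ss <- pos + qs - 1L; se <- pos + qe
    } else {
      ss <- pos + L - qe; se <- pos + L - qs + 1L
    }
    spacers <- spacer_row(sp); spacers$spacer_key <- "k1:1"
    raw <- data.frame(query = "k1:1", subject = "t", qstart = qs, qend = qe,
                      sstart = ss, send = se, strand = strand,
                      gapped = FALSE)
    h <- extend_blast_hit(raw, spacers, target_row("t", tgt),
                          max_mismatches = 10L)
    expect_equal(h$start, pos)
    expect_equal(h$end, pos + L)
    expect_equal(h$mismatches, h_true)
  }
})

test_that("the repeat-contamination filter removes hits on contigs that also
           match the cassette repeat", {
  set.seed(66)
  rep_s <- random_dna_str(30)
  sp <- random_dna_str(34)
  cassettes <- data.frame(cassette_id = "k1", repeat_consensus = rep_s,
                          stringsAsFactors = FALSE)
  # undetected array copy: repeat + spacer on the target contig
  dirty <- target_row("dirty", paste0(random_dna_str(120), rep_s, sp,
                                      rep_s, random_dna_str(120)))
  clean <- target_row("clean", paste0(random_dna_str(120), sp,
                                      random_dna_str(120)))
  targets <- rbind(dirty, clean)
  hits <- scan_targets(spacer_row(sp), targets)
  hits <- repeat_contamination_filter(hits, cassettes, targets)
  expect_false(hits$passed_repeat_filter[hits$target_contig_id == "dirty"])
  expect_true(hits$passed_repeat_filter[hits$target_contig_id == "clean"])
  rel <- reliable_hits(hits)
  expect_equal(rel$target_contig_id, "clean")
})

test_that("pseudospacers avoid cassette intervals, fall back per the 100-nt
           rule, and are seed-reproducible", {
  set.seed(67)
  contig <- target_row("c1", random_dna_str(10000))
  iv <- data.frame(contig_id = "c1", start = 4000L, end = 5000L)
  sp <- spacer_row(substr(contig$sequence, 4200, 4231), contig = "c1",
                   start = 4199L)
  ps <- make_pseudospacers(sp, contig, iv, seed = 9)
  expect_equal(nrow(ps), 1L)
  expect_equal(ps$end - ps$start, 32L)
  expect_true(ps$end <= 4000L || ps$start >= 5000L)
  expect_equal(ps$rule, "same_contig")
  ps2 <- make_pseudospacers(sp, contig, iv, seed = 9)
  expect_identical(ps, ps2)
  # both flanks < 100 nt: fragment comes from a cassette-free contig of the
  # same individual
  small <- target_row("c2", random_dna_str(1160))
  iv2 <- data.frame(contig_id = "c2", start = 80L, end = 1080L)
  free <- target_row("c3", random_dna_str(3000))
  sp2 <- spacer_row(substr(small$sequence, 101, 132), contig = "c2",
                    start = 100L)
  ps3 <- make_pseudospacers(sp2, rbind(small, free), iv2, seed = 9)
  expect_equal(ps3$contig_id, "c3")
  expect_equal(ps3$rule, "fallback_contig")
  # no cassette-free contig available: skipped with a warning
  expect_warning(
    ps4 <- make_pseudospacers(sp2, small, iv2, seed = 9), "skipped")
  expect_equal(nrow(ps4), 0L)
})

test_that("the pseudospacer flank filter discards homology-driven pairs", {
  set.seed(68)
  rep_len <- 30L
  cassettes <- data.frame(cassette_id = "k1",
                          repeat_consensus = random_dna_str(rep_len),
                          stringsAsFactors = FALSE)
  core <- random_dna_str(36)
  left_fl <- random_dna_str(rep_len); right_fl <- random_dna_str(rep_len)
  # conserved gene present in both the pseudospacer source and the target
  src <- target_row("src", paste0(random_dna_str(200), left_fl, core,
                                  right_fl, random_dna_str(200)))
  tgt_hom <- target_row("hom", paste0(random_dna_str(150), left_fl, core,
                                      random_dna_str(150)))
  tgt_clean <- target_row("cln", paste0(random_dna_str(150), core,
                                        random_dna_str(150)))
  pseudo <- data.frame(cassette_id = "k1", contig_id = "src", serial = 1L,
                       start = 200L + rep_len, end = 200L + rep_len + 36L,
                       sequence = core, rule = "same_contig",
                       stringsAsFactors = FALSE)
  pseudo$provisional <- FALSE; pseudo$canonical <- canonical_seq(core)
  targets <- rbind(tgt_hom, tgt_clean)
  hits <- scan_targets(pseudo, targets)
  expect_equal(nrow(hits), 2L)
  kept <- pseudo_flank_filter(hits, pseudo, cassettes, rbind(src, targets),
                              targets)
  expect_equal(kept$target_contig_id, "cln")
  # degenerate input passes through
  expect_equal(nrow(pseudo_flank_filter(hits[0, ], pseudo, cassettes,
                                        rbind(src, targets))), 0L)
})

test_that("PAM scanning reports perfectly conserved flanks and stays quiet on
           uniform ones", {
  set.seed(69)
  mkhits <- function(n, left) data.frame(
    spacer_key = paste0("k", seq_len(n), ":1"),
    cassette_id = paste0("k", seq_len(n)),
    flank_left = left, flank_right = vapply(seq_len(n), function(i)
      random_dna_str(10), ""),
    strand = "+", stringsAsFactors = FALSE)
  clusters <- data.frame(cassette_id = paste0("k", 1:20),
                         cluster_id = "RC001", stringsAsFactors = FALSE)
  conserved <- mkhits(10, paste0("TTC", vapply(1:10, function(i)
    random_dna_str(7), "")))
  fl <- extract_pam_flanks(conserved, clusters)
  res <- pam_scan(fl)
  left <- res[res$side == "left", ]
  expect_false(is.na(left$motif))
  # left flanks are protospacer-proximal aligned (right-aligned), so with the
  # conserved TTC at flank start the motif sits 7 positions from the spacer
  expect_match(left$motif, "TTC")
  uniform <- mkhits(20, vapply(1:20, function(i) random_dna_str(10), ""))
  res2 <- pam_scan(extract_pam_flanks(uniform, clusters))
  expect_true(all(is.na(res2$motif)))
  # groups under the size gate are skipped
  two <- mkhits(2, c("TTCAAAAAAA", "TTCCCCCCCC"))
  expect_equal(nrow(pam_scan(extract_pam_flanks(two, clusters))), 0L)
})
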