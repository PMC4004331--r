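mk_spacer <- function(cassette, serial, contig, seq) {
  data.frame(cassette_id = cassette, contig_id = contig, serial = serial,
             start = serial * 100L, end = serial * 100L + nchar(seq),
             sequence = seq, provisional = FALSE,
             canonical = canonical_seq(seq), stringsAsFactors = FALSE)
}

mk_hit <- function(cassette, serial, target) {
  data.frame(spacer_key = paste(cassette, serial, sep = ":"),
             cassette_id = cassette, serial = serial,
             target_contig_id = target, start = 0L, end = 30L, strand = "+",
             mismatches = 0L, flank_left = "", flank_right = "",
             source = "internal_scan", passed_repeat_filter = TRUE,
             stringsAsFactors = FALSE)
}

mk_contig_tbl <- function(ids, inds) {
  data.frame(contig_id = ids, individual_id = inds, dataset = "SYN",
             sequence = "", length = 0L, stringsAsFactors = FALSE)
}

test_that("the pair matrix counts protospacer rows by spacer columns", {
  contigs <- mk_contig_tbl(c("cA", "cB", "pA", "pB"),
                           c("A", "B", "A", "B"))
  spacers <- rbind(mk_spacer("k1", 1, "cA", "ACGTACGTACGTACGTACGTACGTA"),
                   mk_spacer("k2", 1, "cB", "TGCATGCATGCATGCATGCATGCAT"))
  hits <- rbind(mk_hit("k1", 1, "pA"), mk_hit("k1", 1, "pA"),
                mk_hit("k1", 1, "pA"), mk_hit("k2", 1, "pA"))
  m <- build_pair_matrix(hits, spacers, contigs)
  expect_equal(sum(m), 4L)
  expect_equal(m["A", "A"], 3L) # three within-individual pairs
  expect_equal(m["A", "B"], 1L) # spacer in B, protospacer in A
  expect_equal(m["B", "B"], 0L)
  empty <- build_pair_matrix(hits[0, ], spacers, contigs)
  expect_true(all(empty == 0L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pair_matrix(m, f)
  m2 <- read_pair_matrix(f)
  expect_equal(unclass(m2), unclass(m), ignore_attr = TRUE)
  expect_equal(rownames(m2), rownames(m))
})

test_that("targeting and shared spacer definitions follow the individuals", {
  contigs <- mk_contig_tbl(c("cA", "cB", "pA", "pB"),
                           c("A", "B", "A", "B"))
  s_shared <- "ACGTACGTACGTACGTACGTACGTA"
  spacers <- rbind(mk_spacer("k1", 1, "cA", s_shared),
                   mk_spacer("k1", 2, "cA", "TTTTGGGGCCCCAAAATTTTGGGGC"),
                   mk_spacer("k2", 1, "cB", s_shared))
  hits <- rbind(mk_hit("k1", 1, "pA"),  # own individual -> targeting
                mk_hit("k1", 2, "pB"))  # other individual only -> not
  cl <- classify_spacers(spacers, hits, contigs)
  expect_equal(cl$targeting, c(TRUE, FALSE, FALSE))
  # identical sequence in individuals A and B: both occurrences shared
  expect_equal(cl$shared, c(TRUE, FALSE, TRUE))
})

test_that("position test matches exact enumeration on one small cassette", {
  cassettes <- data.frame(cassette_id = "k1", complete = TRUE,
                          leader_end = "left", stringsAsFactors = FALSE)
  spacers <- do.call(rbind, lapply(1:5, function(s)
    mk_spacer("k1", s, "cA", random_dna_str(30))))
  spacers$targeting <- spacers$serial == 1
  r <- position_permutation_test(spacers, cassettes, "targeting",
                                 n_perm = 10000, seed = 2)
  expect_equal(r$observed, 1)
  # exact lower-tail p is 1/5; the Monte-Carlo estimate sits within 3 SE
  se <- sqrt(0.2 * 0.8 / 10000)
  expect_lt(abs(r$p_value - 0.2), 3 * se)
  expect_equal(r$p_value, r$n_as_extreme / r$n_perm)
})

test_that("an all-flagged cassette set gives a constant statistic and p = 1", {
  cassettes <- data.frame(cassette_id = c("k1", "k2"), complete = TRUE,
                          leader_end = c("left", "right"),
                          stringsAsFactors = FALSE)
  spacers <- rbind(
    do.call(rbind, lapply(1:4, function(s)
      mk_spacer("k1", s, "cA", random_dna_str(30)))),
    do.call(rbind, lapply(1:3, function(s)
      mk_spacer("k2", s, "cB", random_dna_str(30)))))
  spacers$targeting <- TRUE
  lo <- position_permutation_test(spacers, cassettes, "targeting",
                                  n_perm = 500, seed = 3, tail = "lower")
  up <- position_permutation_test(spacers, cassettes, "targeting",
                                  n_perm = 500, seed = 3, tail = "upper")
  expect_equal(lo$p_value, 1)
  expect_equal(up$p_value, 1)
  expect_equal(lo$null_sd, 0)
})

test_that("position test filters to complete, oriented cassettes and errors
           when nothing is eligible", {
  cassettes <- data.frame(cassette_id = c("k1", "k2"),
                          complete = c(FALSE, TRUE),
                          leader_end = c("left", "unknown"),
                          stringsAsFactors = FALSE)
  spacers <- rbind(mk_spacer("k1", 1, "cA", random_dna_str(30)),
                   mk_spacer("k2", 1, "cB", random_dna_str(30)))
  spacers$targeting <- TRUE
  expect_error(position_permutation_test(spacers, cassettes, "targeting",
                                         n_perm = 10, seed = 1),
               "complete")
})

test_that("two seeds give position-test p estimates within 4 MC SE", {
  set.seed(42)
  cassettes <- data.frame(cassette_id = paste0("k", 1:8), complete = TRUE,
                          leader_end = "left", stringsAsFactors = FALSE)
  spacers <- do.call(rbind, lapply(paste0("k", 1:8), function(k)
    do.call(rbind, lapply(1:8, function(s)
      mk_spacer(k, s, "cA", random_dna_str(30))))))
  spacers$targeting <- runif(nrow(spacers)) < 0.3
  r1 <- position_permutation_test(spacers, cassettes, "targeting",
                                  n_perm = 20000, seed = 1)
  r2 <- position_permutation_test(spacers, cassettes, "targeting",
                                  n_perm = 20000, seed = 2)
  se <- sqrt(r1$p_value * (1 - r1$p_value) / 20000)
  expect_lt(abs(r1$p_value - r2$p_value), 4 * max(se, 1e-3))
})

test_that("sharing test: disjoint spacer sets give a constant null at zero", {
  ci <- data.frame(cassette_id = c("k1", "k2"), individual_id = c("A", "B"),
                   stringsAsFactors = FALSE)
  spacers <- rbind(mk_spacer("k1", 1, "cA", "ACGTACGTACGTACGTACGTACGTA"),
                   mk_spacer("k2", 1, "cB", "GGGGCCCCAAAATTTTGGGGCCCCA"))
  r <- sharing_permutation_test(spacers, ci, n_perm = 200, seed = 1)
  expect_equal(r$observed, 0)
  expect_equal(r$null_sd, 0)
  expect_equal(r$p_value, 1)
  expect_error(sharing_permutation_test(
    spacers, data.frame(cassette_id = c("k1", "k2"), individual_id = "A"),
    n_perm = 10, seed = 1), "2 individuals")
})

test_that("sharing null redistributes whole cassettes: support respects the
           fixed cassette contents", {
  # sequence s occurs in cassettes k1 and k2; with 4 cassettes over 2
  # individuals every permutation keeps per-individual cassette counts, and
  # the shared count can only be 0 or 1
  s <- "ACGTACGTACGTACGTACGTACGTA"
  ci <- data.frame(cassette_id = paste0("k", 1:4),
                   individual_id = c("A", "A", "B", "B"),
                   stringsAsFactors = FALSE)
  spacers <- rbind(mk_spacer("k1", 1, "c1", s),
                   mk_spacer("k2", 1, "c2", s),
                   mk_spacer("k3", 1, "c3", "GGGGCCCCAAAATTTTGGGGCCCCA"),
                   mk_spacer("k4", 1, "c4", "TTAATTAATTAACCGGCCGGCCGGA"))
  r <- sharing_permutation_test(spacers, ci, n_perm = 3000, seed = 5)
  # k1 and k2 both belong to A: the observed shared count is 0
  expect_equal(r$observed, 0)
  # exact null: P(k1, k2 land in different individuals) = 2/3
  expect_lt(abs(r$null_mean - 2 / 3), 0.03)
  # lower-tail p = P(shared <= 0) = 1/3 exactly
  expect_lt(abs(r$p_value - 1 / 3), 0.03)
})

test_that("CMH closed form matches hand oracle and mantelhaen.test in both
           correction modes, and ignores individual labels", {
  # hand-evaluated single stratum (10,0,0,10): E = 5, V = 25/19 -> 19.0
  expect_equal(cmh_statistic(array(c(10, 0, 0, 10), dim = c(2, 2, 1))), 19.0)
  # proportional stratum: a equals its expectation -> 0
  expect_equal(cmh_statistic(array(c(4, 2, 6, 3), dim = c(2, 2, 1))), 0)
  set.seed(7)
  inds <- LETTERS[1:6]
  pairs <- data.frame(spacer_individual = sample(inds, 80, TRUE),
                      proto_individual = sample(inds, 80, TRUE))
  arr <- array(0, dim = c(2, 2, 6))
  for (k in seq_along(inds)) {
    s <- pairs$spacer_individual == inds[k]
    p <- pairs$proto_individual == inds[k]
    arr[, , k] <- matrix(c(sum(s & p), sum(s & !p), sum(!s & p),
                           sum(!s & !p)), 2, byrow = TRUE)
  }
  expect_equal(cmh_statistic(pairs),
               unname(stats::mantelhaen.test(arr, correct = FALSE)$statistic))
  expect_equal(cmh_statistic(pairs, correct = TRUE),
               unname(stats::mantelhaen.test(arr, correct = TRUE)$statistic))
  # relabeling invariance
  relab <- pairs
  map <- setNames(rev(inds), inds)
  relab$spacer_individual <- map[relab$spacer_individual]
  relab$proto_individual <- map[relab$proto_individual]
  expect_equal(cmh_statistic(relab), cmh_statistic(pairs))
  expect_error(cmh_statistic(array(c(5, 0, 0, 0), dim = c(2, 2, 1))),
               "degenerate")
})

test_that("a perfectly diagonal pair list is highly significant under the
           protospacer shuffle", {
  pairs <- data.frame(spacer_individual = rep(LETTERS[1:3], each = 8),
                      proto_individual = rep(LETTERS[1:3], each = 8))
  r <- cmh_permutation_test(pairs, n_perm = 2000, seed = 4)
  expect_lte(r$p_value, 0.01)
  expect_equal(r$p_value, r$n_as_extreme / r$n_perm)
})

test_that("under an exchangeable null the protospacer-shuffle p-values are
           calibrated (conservative at worst)", {
  set.seed(123)
  p <- replicate(200, {
    pairs <- data.frame(
      spacer_individual = sample(LETTERS[1:10], 150, TRUE),
      proto_individual = sample(LETTERS[1:10], 150, TRUE))
    cmh_permutation_test(pairs, n_perm = 400,
                         seed = sample.int(1e6, 1))$p_value
  })
  se05 <- sqrt(0.05 * 0.95 / 200)
  expect_lte(mean(p <= 0.05), 0.05 + 3 * se05)
  expect_gte(mean(p <= 0.25), 0.10) # not degenerate either
  expect_gt(mean(p), 0.40)
  expect_lt(mean(p), 0.62)
})

test_that("majority-foreign counting uses a strict majority over columns with
           pairs", {
  m <- matrix(0L, 3, 3, dimnames = list(protospacer = c("A", "B", "C"),
                                        spacer = c("A", "B", "C")))
  m["A", "A"] <- 5L; m["B", "A"] <- 2L     # A: self 5 > foreign 2 -> no
  m["C", "B"] <- 1L                        # B: self 0 < foreign 1 -> yes
  # C: no pairs at all -> not considered
  res <- majority_foreign_count(structure(m, class = c("pair_matrix",
                                                       class(m))))
  expect_equal(res$count, 1L)
  expect_equal(res$n_considered, 2L)
  expect_equal(res$fraction_all, 1 / 3)
})
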