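# The three permutation analyses and the individuals x individuals pair
# matrix behind them. p-values are reported as plain fractions k/n of
# permutations at least as extreme (the add-one convention is carried
# alongside as p_value_add1).

perm_test_result <- function(observed, null, tail, n_perm, seed) {
  k <- switch(tail,
              lower = sum(null <= observed),
              upper = sum(null >= observed),
              two_sided = sum(abs(null - mean(null)) >=
                                abs(observed - mean(null))))
  structure(list(observed = observed, n_perm = n_perm, n_as_extreme = k,
                 p_value = k / n_perm, p_value_add1 = (k + 1) / (n_perm + 1),
                 tail = tail, seed = seed,
                 null_mean = mean(null), null_sd = stats::sd(null)),
            class = "perm_test_result")
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test: observed %.4g, null %.4g +/- %.4g (%d perms, %s tail)\n",
    x$observed, x$null_mean, x$null_sd, x$n_perm, x$tail))
  cat(sprintf("  p = %.5g (plain fraction; add-one: %.5g), seed %d\n",
              x$p_value, x$p_value_add1, x$seed))
  invisible(x)
}

#' Individuals-by-individuals spacer-protospacer pair matrix
#'
#' Entry (i, j) counts reliable spacer-protospacer pairs whose protospacer
#' lies in individual i's metagenome and whose spacer lies in individual j's
#' cassettes (rows = protospacer metagenomes, columns = spacer metagenomes).
#'
#' @param hits reliable hit table.
#' @param spacers spacer table (`contig_id` locates the spacer's contig).
#' @param contigs contig table mapping contigs to individuals.
#' @param individuals optional ordered character vector of individual ids;
#'   defaults to all individuals seen in `contigs`.
#' @return an integer matrix of class `pair_matrix`.
#' @export
build_pair_matrix <- function(hits, spacers, contigs, individuals = NULL) {
  sp_key <- paste(spacers$cassette_id, spacers$serial, sep = ":")
  sp_ind <- contigs$individual_id[match(spacers$contig_id, contigs$contig_id)]
  spacer_ind <- setNames(sp_ind, sp_key)
  proto_ind <- contigs$individual_id[match(hits$target_contig_id,
                                           contigs$contig_id)]
  s_ind <- unname(spacer_ind[hits$spacer_key])
  bad <- is.na(s_ind) | is.na(proto_ind)
  if (any(bad)) {
    message(sum(bad), " pair(s) with unknown individual excluded")
    s_ind <- s_ind[!bad]; proto_ind <- proto_ind[!bad]
  }
  if (is.null(individuals))
    individuals <- sort(unique(contigs$individual_id))
  m <- table(factor(proto_ind, levels = individuals),
             factor(s_ind, levels = individuals))
  m <- matrix(as.integer(m), nrow = length(individuals),
              dimnames = list(protospacer = individuals,
                              spacer = individuals))
  structure(m, class = c("pair_matrix", class(m)))
}

#' @export
print.pair_matrix <- function(x, ...) {
  print(matrix(as.integer(x), nrow = nrow(x), dimnames = dimnames(x)), ...)
  invisible(x)
}

#' Read a pair matrix TSV (rows = protospacer metagenomes, columns = spacer
#' metagenomes; first column holds the row labels)
#' @param path file path.
#' @return `pair_matrix`.
#' @export
read_pair_matrix <- function(path) {
  x <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  rn <- x[[1]]
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- rn
  if (!identical(sort(rownames(m)), sort(colnames(m))))
    stop("pair matrix rows and columns must index the same individuals")
  m <- m[colnames(m), , drop = FALSE] # align row order to columns
  names(dimnames(m)) <- c("protospacer", "spacer")
  structure(m, class = c("pair_matrix", class(m)))
}

#' Write a pair matrix TSV (inverse of [read_pair_matrix()])
#' @param m `pair_matrix`.
#' @param path output path.
#' @export
write_pair_matrix <- function(m, path) {
  df <- data.frame(individual = rownames(m), as.data.frame(unclass(m),
                   check.names = FALSE), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

pairs_from_matrix <- function(m) {
  idx <- which(m > 0, arr.ind = TRUE)
  data.frame(
    proto_individual = rep(rownames(m)[idx[, 1]], m[idx]),
    spacer_individual = rep(colnames(m)[idx[, 2]], m[idx]),
    stringsAsFactors = FALSE)
}

#' Flag targeting and shared spacers
#'
#' Targeting: the spacer has at least one reliable protospacer in the same
#' individual metagenome. Shared: the spacer's canonical sequence occurs in
#' cassettes of two or more distinct individuals (every occurrence of such a
#' sequence is flagged).
#'
#' @param spacers spacer table.
#' @param hits reliable hit table.
#' @param contigs contig table (individual assignment).
#' @return the spacer table with logical columns `targeting` and `shared`
#'   and an `individual_id` column.
#' @export
classify_spacers <- function(spacers, hits, contigs) {
  spacers$individual_id <- contigs$individual_id[
    match(spacers$contig_id, contigs$contig_id)]
  sp_key <- paste(spacers$cassette_id, spacers$serial, sep = ":")
  proto_ind <- contigs$individual_id[match(hits$target_contig_id,
                                           contigs$contig_id)]
  spacer_ind <- spacers$individual_id[match(hits$spacer_key, sp_key)]
  same <- hits$spacer_key[!is.na(proto_ind) & !is.na(spacer_ind) &
                            proto_ind == spacer_ind]
  spacers$targeting <- sp_key %in% same
  n_ind <- vapply(split(spacers$individual_id, spacers$canonical),
                  function(x) length(unique(x)), 0L)
  spacers$shared <- n_ind[spacers$canonical] >= 2
  spacers
}

#' Leader-position Monte-Carlo test
#'
#' For every complete, oriented cassette with at least one flagged spacer,
#' the serial numbers (counted from the leader) of the flagged spacers are
#' summed; the statistic is the total over cassettes. Under the null, the
#' flagged labels are shuffled uniformly over positions within each cassette
#' (flag counts per cassette fixed). Targeting spacers concentrating near
#' the leader push the observed sum into the lower tail; shared spacers
#' drifting to the trailer push it into the upper tail.
#'
#' @param spacers spacer table with a logical flag column.
#' @param cassettes cassette table (`complete`, `leader_end`).
#' @param flag `"targeting"` or `"shared"` (names the flag column; any
#'   logical column works).
#' @param n_perm permutations (default 100000).
#' @param seed RNG seed.
#' @param tail `"lower"` (default for targeting), `"upper"` (default for
#'   shared), or explicit.
#' @return a `perm_test_result`.
#' @export
position_permutation_test <- function(spacers, cassettes, flag = "targeting",
                                      n_perm = 100000L, seed = 1L,
                                      tail = NULL) {
  if (is.null(tail))
    tail <- if (flag == "shared") "upper" else "lower"
  eligible <- cassettes$cassette_id[cassettes$complete &
                                      cassettes$leader_end %in%
                                      c("left", "right")]
  sp <- spacers[spacers$cassette_id %in% eligible, , drop = FALSE]
  fl <- sp[[flag]]
  if (is.null(fl)) stop("no flag column '", flag, "' in spacer table")
  per_cas <- split(fl, sp$cassette_id)
  per_cas <- per_cas[vapply(per_cas, any, TRUE)]
  if (!length(per_cas))
    stop("no eligible cassettes: need complete = TRUE, known leader_end, ",
         "and at least one '", flag, "' spacer")
  keep <- sp$cassette_id %in% names(per_cas)
  observed <- sum(sp$serial[keep & fl])
  n <- vapply(per_cas, length, 0L)
  k <- vapply(per_cas, sum, 0L)
  set.seed(seed)
  null <- perm_position_sums(n, k, as.integer(n_perm))
  perm_test_result(observed, null, tail, n_perm, seed)
}

#' Cassette-shuffle spacer-sharing test
#'
#' The observed statistic is the number of distinct canonical spacer
#' sequences present in two or more individuals. The null redistributes
#' whole cassettes across individuals while preserving each individual's
#' cassette count (a permutation of the cassette-to-individual labels); the
#' paper-style alternative is that real sharing is below the shuffled
#' expectation, so the lower tail is reported.
#'
#' @param spacers spacer table (needs `cassette_id`, `canonical`).
#' @param cassette_individuals data.frame `cassette_id`, `individual_id`.
#' @param n_perm permutations (default 100000).
#' @param seed RNG seed.
#' @param tail default `"lower"`.
#' @return a `perm_test_result`.
#' @export
sharing_permutation_test <- function(spacers, cassette_individuals,
                                     n_perm = 100000L, seed = 1L,
                                     tail = "lower") {
  ids <- cassette_individuals$cassette_id
  if (length(unique(cassette_individuals$individual_id)) < 2)
    stop("sharing test needs at least 2 individuals")
  labels <- as.integer(factor(cassette_individuals$individual_id))
  cas_index <- match(spacers$cassette_id, ids)
  if (anyNA(cas_index)) stop("spacer with unknown cassette")
  groups <- split(cas_index, spacers$canonical)
  groups <- lapply(groups, unique)
  groups <- groups[lengths(groups) >= 2] # single-cassette sequences can
  # never be shared under any relabeling
  observed <- sum(vapply(groups, function(g)
    length(unique(labels[g])) >= 2, TRUE))
  set.seed(seed)
  null <- if (length(groups))
    perm_shared_counts(labels, unname(groups), as.integer(n_perm))
  else rep(0L, n_perm)
  perm_test_result(observed, as.numeric(null), tail, n_perm, seed)
}

cmh_components <- function(x) {
  if (is.array(x) && length(dim(x)) == 3 && all(dim(x)[1:2] == 2)) {
    # explicit 2x2xK strata: rows = spacer in/out, cols = protospacer in/out
    a <- x[1, 1, ]; r1 <- x[1, 1, ] + x[1, 2, ]; c1 <- x[1, 1, ] + x[2, 1, ]
    nk <- apply(x, 3, sum)
    pairs <- NULL; strata <- seq_along(a)
  } else {
    if (inherits(x, "pair_matrix") || (is.matrix(x) && nrow(x) == ncol(x))) {
      pairs <- pairs_from_matrix(x)
      strata <- colnames(x)
    } else {
      pairs <- x
      strata <- sort(unique(c(pairs$spacer_individual,
                              pairs$proto_individual)))
    }
    n <- nrow(pairs)
    a <- vapply(strata, function(k)
      sum(pairs$spacer_individual == k & pairs$proto_individual == k), 0)
    r1 <- vapply(strata, function(k) sum(pairs$spacer_individual == k), 0)
    c1 <- vapply(strata, function(k) sum(pairs$proto_individual == k), 0)
    nk <- rep(n, length(strata))
  }
  E <- ifelse(nk > 0, r1 * c1 / nk, 0)
  V <- ifelse(nk > 1,
              r1 * (nk - r1) * c1 * (nk - c1) / (nk^2 * (nk - 1)), 0)
  list(a = a, E = E, V = V, pairs = pairs, strata = strata)
}

#' Cochran-Mantel-Haenszel statistic over individual strata
#'
#' Each individual k contributes a 2x2 table over all spacer-protospacer
#' pairs: spacer from k or not crossed with protospacer from k or not. The
#' statistic is `(|sum(a_k - E_k)| - 0.5 * correct)^2 / sum(V_k)` with the
#' usual hypergeometric mean and variance; degenerate strata (a zero margin)
#' contribute nothing to either sum.
#'
#' @param x a `pair_matrix` (square count matrix), a pair data.frame with
#'   columns `spacer_individual`, `proto_individual`, or an explicit 2x2xK
#'   stratum array (rows: spacer in/out of stratum, columns: protospacer).
#' @param correct apply the 0.5 continuity correction (default FALSE).
#' @return the CMH chi-square value (1 df).
#' @export
cmh_statistic <- function(x, correct = FALSE) {
  cm <- cmh_components(x)
  denom <- sum(cm$V)
  if (denom == 0) stop("all strata degenerate; CMH undefined")
  num <- abs(sum(cm$a - cm$E)) - if (correct) 0.5 else 0
  unname(num^2 / denom)
}

#' Protospacer-shuffle permutation test for the CMH statistic
#'
#' The null shuffles the multiset of protospacer-individual labels over the
#' pairs (spacer labels fixed), which preserves every individual's
#' protospacer count; the upper-tail p is the fraction of permuted CMH
#' values at least as large as the observed one. Because the stratum margins
#' are invariant under this shuffle, only `sum(a_k)` (the number of
#' within-individual pairs) varies, which makes the permutation exact and
#' cheap.
#'
#' @param x pair matrix or pair data.frame (see [cmh_statistic()]).
#' @param n_perm permutations (default 10000).
#' @param seed RNG seed.
#' @param correct continuity correction, as in [cmh_statistic()].
#' @return a `perm_test_result` with the CMH value as `observed`.
#' @export
cmh_permutation_test <- function(x, n_perm = 10000L, seed = 1L,
                                 correct = FALSE) {
  cm <- cmh_components(x)
  if (is.null(cm$pairs))
    stop("the permutation null needs the pair list; pass a pair matrix or ",
         "pair data.frame")
  denom <- sum(cm$V)
  if (denom == 0) stop("all strata degenerate; CMH undefined")
  corr <- if (correct) 0.5 else 0
  stat_from_sum_a <- function(sa)
    (abs(sa - sum(cm$E)) - corr)^2 / denom
  observed <- stat_from_sum_a(sum(cm$a))
  s_lab <- cm$pairs$spacer_individual
  p_lab <- cm$pairs$proto_individual
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i)
    stat_from_sum_a(sum(s_lab == sample(p_lab))), 0)
  perm_test_result(observed, null, "upper", n_perm, seed)
}

#' Individuals whose protospacers are mostly foreign
#'
#' Over individuals j whose spacers have at least one protospacer pair
#' (column sum > 0), counts those where strictly more pairs have the
#' protospacer in another individual than in j itself.
#'
#' @param m `pair_matrix`.
#' @return list: `count`, `n_considered`, `fraction_considered`,
#'   `fraction_all`.
#' @export
majority_foreign_count <- function(m) {
  cs <- colSums(m)
  self <- diag(as.matrix(unclass(m)))
  considered <- cs > 0
  foreign <- cs - self
  cnt <- sum(considered & foreign > self)
  list(count = cnt, n_considered = sum(considered),
       fraction_considered = cnt / max(1, sum(considered)),
       fraction_all = cnt / ncol(m))
}
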