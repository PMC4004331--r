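#' @useDynLib gutcrispr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats setNames
#' @importFrom utils read.delim write.table head
NULL

# ---------------------------------------------------------------------------
# Coordinate convention: every interval held in memory is 0-based half-open
# [start, end). GFF3, BLAST tabular and the prediction/cas TSVs are converted
# at the I/O boundary (they are 1-based inclusive on disk).
# ---------------------------------------------------------------------------

DATASET_LABELS <- c("JPN", "HMP", "DG", "SYN", "other")
PROGRAM_LABELS <- c("CRT", "CFI", "PIL", "BUILTIN", "OTHER")

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`; `N` is preserved.
#'
#' @param x character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical (strand-insensitive) form of a DNA sequence
#'
#' The lexicographic minimum of a sequence and its reverse complement.
#' Used whenever spacer identity must not depend on the (often unknown)
#' cassette strand: `canonical_seq(s) == canonical_seq(revcomp(s))`.
#'
#' @param x character vector of DNA sequences.
#' @return character vector.
#' @export
canonical_seq <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

# Hamming distance over equal-length strings; N on either side always counts
# as a mismatch (conservative for the 4-mismatch protospacer threshold).
hamming_n <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  if (length(ra) != length(rb)) stop("hamming_n: unequal lengths")
  nn <- charToRaw("N")
  sum(ra != rb | ra == nn | rb == nn)
}

# substring in the internal 0-based half-open convention
substr0 <- function(x, start, end) substr(x, start + 1L, end)

#' Read a contig manifest
#'
#' Tab-separated table with columns `contig_id`, `individual_id` and
#' optionally `dataset`, assigning each contig to the individual metagenome
#' it came from.
#'
#' @param path file path.
#' @return data.frame with columns `contig_id`, `individual_id`, `dataset`.
#' @export
read_manifest <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("contig_id", "individual_id") %in% names(m)))
    stop("manifest must have columns contig_id and individual_id")
  if (is.null(m$dataset)) m$dataset <- "other"
  m[c("contig_id", "individual_id", "dataset")]
}

#' Read assembled contigs from FASTA
#'
#' Individual/dataset assignment comes from `manifest` when supplied;
#' otherwise headers are parsed with the `id|individual[|dataset]` token
#' convention. Sequences are upper-cased. Characters outside `{A,C,G,T,N}`
#' raise an error in strict mode and are mapped to `N` otherwise.
#'
#' @param path FASTA file of contigs.
#' @param manifest optional data.frame from [read_manifest()].
#' @param strict error on duplicate ids and non-ACGTN characters (default
#'   `TRUE`); if `FALSE`, offending characters become `N`.
#' @return data.frame with columns `contig_id`, `individual_id`, `dataset`,
#'   `sequence`, `length`.
#' @export
read_contigs <- function(path, manifest = NULL, strict = TRUE) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty FASTA: ", path)
  hdr <- sub("\\s.*$", "", names(ss))
  toks <- strsplit(hdr, "|", fixed = TRUE)
  ids <- vapply(toks, `[`, "", 1L)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    if (strict) stop("duplicate contig id(s): ", paste(dup, collapse = ", "))
    warning("duplicate contig id(s) kept first: ", paste(dup, collapse = ", "))
    keep <- !duplicated(ids)
    ss <- ss[keep]; toks <- toks[keep]; ids <- ids[keep]
  }
  seqs <- toupper(as.character(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    if (strict) stop("illegal characters in contig(s): ",
                     paste(head(ids[bad], 5), collapse = ", "))
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  ind <- vapply(toks, function(t) if (length(t) >= 2) t[2] else NA_character_, "")
  ds <- vapply(toks, function(t) if (length(t) >= 3) t[3] else NA_character_, "")
  out <- data.frame(contig_id = ids, individual_id = ind, dataset = ds,
                    sequence = unname(seqs), length = nchar(seqs),
                    stringsAsFactors = FALSE)
  if (!is.null(manifest)) {
    i <- match(out$contig_id, manifest$contig_id)
    out$individual_id <- ifelse(is.na(i), out$individual_id, manifest$individual_id[i])
    out$dataset <- ifelse(is.na(i), out$dataset, manifest$dataset[i])
  }
  out$dataset[is.na(out$dataset)] <- "other"
  rownames(out) <- NULL
  out
}

#' Write contigs to FASTA
#'
#' Headers use the `id|individual|dataset` convention so that
#' [read_contigs()] round-trips the assignment without a manifest.
#'
#' @param contigs contig table as returned by [read_contigs()].
#' @param path output path.
#' @export
write_contigs <- function(contigs, path) {
  ss <- Biostrings::DNAStringSet(contigs$sequence)
  names(ss) <- paste(contigs$contig_id, contigs$individual_id, contigs$dataset,
                     sep = "|")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Ingest normalized CRISPR array predictions
#'
#' Exchange format for the outputs of external detectors (one row per repeat
#' copy): columns `contig_id`, `program`, `array_id`, `repeat_start`,
#' `repeat_end` (1-based inclusive on disk) and `consensus`. Rows are grouped
#' into arrays by `(contig_id, program, array_id)`.
#'
#' @param path TSV file path.
#' @param contigs optional contig table used to bound-check coordinates.
#' @return prediction table: one row per repeat copy with columns
#'   `prediction_id`, `contig_id`, `program`, `start`, `end` (0-based
#'   half-open) and `consensus`.
#' @export
ingest_predictions_tsv <- function(path, contigs = NULL) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig_id", "program", "array_id", "repeat_start", "repeat_end")
  if (!all(need %in% names(x)))
    stop("prediction TSV must have columns: ", paste(need, collapse = ", "))
  if (is.null(x$consensus)) x$consensus <- NA_character_
  unknown <- !(x$program %in% PROGRAM_LABELS)
  if (any(unknown)) {
    warning("unknown program label(s) mapped to OTHER: ",
            paste(unique(x$program[unknown]), collapse = ", "))
    x$program[unknown] <- "OTHER"
  }
  x$start <- as.integer(x$repeat_start) - 1L
  x$end <- as.integer(x$repeat_end)
  if (any(is.na(x$start) | is.na(x$end) | x$start < 0 | x$start >= x$end))
    stop("invalid repeat coordinates in ", path)
  x$prediction_id <- paste(x$contig_id, x$program, x$array_id, sep = "/")
  x <- x[order(x$prediction_id, x$start), ]
  for (pid in unique(x$prediction_id)) {
    g <- x[x$prediction_id == pid, ]
    if (nrow(g) < 2)
      stop("array with fewer than 2 repeat copies: ", pid)
    if (any(g$start[-1] < g$end[-nrow(g)]))
      stop("overlapping repeat intervals in array: ", pid)
    if (!is.null(contigs)) {
      len <- contigs$length[match(g$contig_id[1], contigs$contig_id)]
      if (!is.na(len) && any(g$end > len))
        stop("repeat interval beyond contig length in array: ", pid)
    }
  }
  rownames(x) <- NULL
  x[c("prediction_id", "contig_id", "program", "start", "end", "consensus")]
}

#' Write predictions in the normalized exchange TSV
#'
#' Inverse of [ingest_predictions_tsv()] (coordinates back to 1-based
#' inclusive).
#'
#' @param predictions prediction table.
#' @param path output path.
#' @export
write_predictions_tsv <- function(predictions, path) {
  out <- data.frame(
    contig_id = predictions$contig_id,
    program = predictions$program,
    array_id = sub("^.*/", "", predictions$prediction_id),
    repeat_start = predictions$start + 1L,
    repeat_end = predictions$end,
    consensus = predictions$consensus,
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Ingest 12-column BLAST tabular output
#'
#' Standard outfmt-6 columns. Subject coordinates are normalized to 0-based
#' half-open on the plus strand with a strand flag (`sstart > send` on disk
#' marks a minus-strand hit); rows with gap opens are flagged `gapped` and
#' left to downstream policy.
#'
#' @param path tabular file path.
#' @return data.frame of raw hit records (`query`, `subject`, `pident`,
#'   `length`, `mismatch`, `gapped`, `qstart`, `qend` 1-based on the query,
#'   `sstart`, `send` 0-based half-open plus-strand, `strand`, `evalue`,
#'   `bitscore`).
#' @export
ingest_blast_tab <- function(path) {
  cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (file.size(path) == 0) {
    warning("empty BLAST tabular file: ", path)
    out <- as.data.frame(setNames(rep(list(character(0)), 12), cols))
    out$strand <- character(0); out$gapped <- logical(0)
    return(out)
  }
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) != 12) stop("expected 12 columns, got ", ncol(x))
  names(x) <- cols
  num <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
           "sstart", "send", "evalue", "bitscore")
  for (cc in num) {
    x[[cc]] <- suppressWarnings(as.numeric(x[[cc]]))
    if (anyNA(x[[cc]])) stop("non-numeric values in column ", cc)
  }
  minus <- x$sstart > x$send
  s0 <- ifelse(minus, x$send, x$sstart) - 1L
  e0 <- ifelse(minus, x$sstart, x$send)
  x$strand <- ifelse(minus, "-", "+")
  x$sstart <- as.integer(s0)
  x$send <- as.integer(e0)
  x$gapped <- x$gapopen > 0
  x$gapopen <- NULL
  x
}

#' Read a cas-gene annotation TSV
#'
#' Columns `contig_id`, `gene`, `start`, `end` (1-based inclusive on disk)
#' and `strand`.
#'
#' @param path file path.
#' @return data.frame with 0-based half-open `start`, `end`.
#' @export
read_cas_tsv <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig_id", "gene", "start", "end", "strand")
  if (!all(need %in% names(x)))
    stop("cas TSV must have columns: ", paste(need, collapse = ", "))
  x$gene <- tolower(x$gene)
  x$start <- as.integer(x$start) - 1L
  x$end <- as.integer(x$end)
  if (any(x$start < 0 | x$start >= x$end)) stop("invalid cas gene interval")
  x
}

#' Write cas annotations (inverse of [read_cas_tsv()])
#' @param cas cas annotation table (0-based half-open).
#' @param path output path.
#' @export
write_cas_tsv <- function(cas, path) {
  out <- cas
  out$start <- out$start + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a cassette set as GFF3
#'
#' One `repeat_region` feature per cassette with `direct_repeat` and
#' `binding_site` (spacer) children. Attributes carry `acceptance_rule`,
#' `programs`, `leader_end`, `repeat_consensus`, `cas_adjacent` and
#' `complete`; spacer children carry their `sequence` and `serial` so the
#' file round-trips through [read_cassette_gff()].
#'
#' @param cassette_set list with elements `cassettes`, `repeats`, `spacers`
#'   (see [consensus_filter()]).
#' @param path output path.
#' @export
write_cassette_gff <- function(cassette_set, path) {
  cs <- cassette_set$cassettes
  gr_parent <- GenomicRanges::GRanges(
    seqnames = cs$contig_id,
    ranges = IRanges::IRanges(start = cs$start + 1L, end = cs$end),
    type = "repeat_region",
    ID = cs$cassette_id,
    acceptance_rule = cs$acceptance_rule,
    programs = cs$programs,
    leader_end = cs$leader_end,
    repeat_consensus = cs$repeat_consensus,
    cas_adjacent = as.character(cs$cas_adjacent),
    complete = as.character(cs$complete))
  rp <- cassette_set$repeats
  gr_rep <- GenomicRanges::GRanges(
    seqnames = rp$contig_id,
    ranges = IRanges::IRanges(start = rp$start + 1L, end = rp$end),
    type = "direct_repeat",
    Parent = rp$cassette_id)
  sp <- cassette_set$spacers
  gr_sp <- GenomicRanges::GRanges(
    seqnames = sp$contig_id,
    ranges = IRanges::IRanges(start = sp$start + 1L, end = sp$end),
    type = "binding_site",
    Parent = sp$cassette_id,
    serial = as.character(sp$serial),
    sequence = sp$sequence)
  gr <- suppressWarnings(c(gr_parent, gr_rep, gr_sp))
  gr$source <- "gutcrispr"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a cassette GFF3 written by [write_cassette_gff()]
#'
#' @param path GFF3 path.
#' @return cassette set list (`cassettes`, `repeats`, `spacers`) with 0-based
#'   half-open internal coordinates.
#' @export
read_cassette_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  is_cas <- md$type == "repeat_region"
  first_chr <- function(x) if (length(x)) as.character(x)[1] else NA_character_
  parent_of <- function(i) first_chr(md$Parent[[i]])
  cassettes <- data.frame(
    cassette_id = as.character(md$ID[is_cas]),
    contig_id = as.character(GenomicRanges::seqnames(gr)[is_cas]),
    start = GenomicRanges::start(gr)[is_cas] - 1L,
    end = GenomicRanges::end(gr)[is_cas],
    repeat_consensus = as.character(md$repeat_consensus[is_cas]),
    programs = as.character(md$programs[is_cas]),
    acceptance_rule = as.character(md$acceptance_rule[is_cas]),
    cas_adjacent = as.logical(md$cas_adjacent[is_cas]),
    leader_end = as.character(md$leader_end[is_cas]),
    complete = as.logical(md$complete[is_cas]),
    stringsAsFactors = FALSE)
  ir <- which(md$type == "direct_repeat")
  repeats <- data.frame(
    cassette_id = vapply(ir, parent_of, ""),
    contig_id = as.character(GenomicRanges::seqnames(gr)[ir]),
    start = GenomicRanges::start(gr)[ir] - 1L,
    end = GenomicRanges::end(gr)[ir],
    stringsAsFactors = FALSE)
  isp <- which(md$type == "binding_site")
  spacers <- data.frame(
    cassette_id = vapply(isp, parent_of, ""),
    contig_id = as.character(GenomicRanges::seqnames(gr)[isp]),
    start = GenomicRanges::start(gr)[isp] - 1L,
    end = GenomicRanges::end(gr)[isp],
    serial = as.integer(as.character(md$serial[isp])),
    sequence = as.character(md$sequence[isp]),
    stringsAsFactors = FALSE)
  spacers$canonical <- canonical_seq(spacers$sequence)
  spacers <- spacers[order(spacers$cassette_id, spacers$start), ]
  repeats <- repeats[order(repeats$cassette_id, repeats$start), ]
  rownames(spacers) <- rownames(repeats) <- NULL
  list(cassettes = cassettes, repeats = repeats, spacers = spacers)
}

#' Read the cohort manifest of individuals per dataset
#'
#' The packaged default (`cohort_manifest_synthetic_ids.tsv`) lists the
#' combined human-gut cohort: 124 HMP, 13 JPN and 2 DG individuals (139 in
#' total). Only some JPN labels are public; all other individual ids in the
#' packaged file are synthetic placeholders, as the filename says.
#'
#' @param path TSV with columns `individual_id`, `dataset`; defaults to the
#'   packaged cohort manifest.
#' @return data.frame with one row per individual.
#' @export
read_individuals <- function(path = system.file("extdata",
    "cohort_manifest_synthetic_ids.tsv", package = "gutcrispr")) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("individual_id", "dataset") %in% names(x)))
    stop("individual manifest needs columns individual_id, dataset")
  if (anyDuplicated(x$individual_id))
    stop("duplicate individual ids in manifest")
  x
}
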