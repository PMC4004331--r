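# Rule-based taxonomic labeling of contigs from ranked BLASTX-style hit
# tables (already e-value filtered upstream), plus label transfer from
# protospacer-containing contigs to spacers and label comparison.

taxonomy_label <- function(rank, name, reason, lineage = NULL) {
  structure(list(rank = rank, name = name, reason = reason,
                 lineage = lineage), class = "taxonomy_label")
}

#' @export
print.taxonomy_label <- function(x, ...) {
  cat(sprintf("TaxonomyLabel: %s%s (%s)\n", x$rank,
              if (nzchar(x$name %||% "")) paste0(" ", x$name) else "",
              x$reason))
  invisible(x)
}

#' Assign a contig taxonomy from ranked hits
#'
#' Deepest assignable rank wins: genus, family or class by strict majority
#' (> half) of the top 30 hits (or of all hits when fewer exist); phylum by
#' unanimity of the top 10 (of all hits when fewer than 10 exist).
#' Taxonomically diverse but all-bacterial hits give the nonspecific
#' "Bacteria" label; an empty hit list gives no label.
#'
#' @param hits data.frame sorted by descending score with columns
#'   `rank_index`, `phylum`, `class`, `family`, `genus` (any may be `NA`),
#'   `origin` (`bacterial`, `phage` or `plasmid`) and `score`.
#' @return a `taxonomy_label`; attribute `audit` carries the majority counts
#'   at every rank.
#' @export
assign_contig_taxon <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0)
    return(taxonomy_label("none", "", "no_hits"))
  hits <- hits[order(hits$rank_index), , drop = FALSE]
  top30 <- hits[seq_len(min(30L, nrow(hits))), , drop = FALSE]
  top10 <- hits[seq_len(min(10L, nrow(hits))), , drop = FALSE]
  audit <- list()
  majority_name <- function(values) {
    values <- values[!is.na(values)]
    if (!length(values)) return(NULL)
    tab <- sort(table(values), decreasing = TRUE)
    list(name = names(tab)[1], count = tab[[1]])
  }
  lineage_at <- function(rank, name) {
    row <- top30[which(top30[[rank]] == name)[1], ]
    c(phylum = row$phylum, class = row$class, family = row$family,
      genus = row$genus)[c("phylum", "class", "family", "genus")]
  }
  for (rank in c("genus", "family", "class")) {
    mj <- majority_name(top30[[rank]])
    audit[[rank]] <- mj
    if (!is.null(mj) && mj$count > nrow(top30) / 2) {
      lab <- taxonomy_label(rank, mj$name, "top30_majority",
                            lineage_at(rank, mj$name))
      attr(lab, "audit") <- audit
      return(lab)
    }
  }
  ph <- unique(top10$phylum[!is.na(top10$phylum)])
  if (length(ph) == 1 && !anyNA(top10$phylum)) {
    lab <- taxonomy_label("phylum", ph, "top10_phylum",
                          c(phylum = ph, class = NA, family = NA, genus = NA))
    attr(lab, "audit") <- audit
    return(lab)
  }
  if (all(hits$origin == "bacterial")) {
    lab <- taxonomy_label("domain_nonspecific", "", "diverse")
  } else {
    lab <- taxonomy_label("none", "", "diverse")
  }
  attr(lab, "audit") <- audit
  lab
}

#' Transfer a protospacer's taxonomy to its spacer
#'
#' Phage or plasmid protospacer contigs pass their host's label on;
#' bacterial protospacer contigs pass their own label.
#'
#' @param target_label `taxonomy_label` of the protospacer-containing contig.
#' @param origin `bacterial`, `phage` or `plasmid`.
#' @param host_label `taxonomy_label` of the known host for phage/plasmid
#'   contigs, or `NULL` when the host is unknown.
#' @return a `taxonomy_label`.
#' @export
transfer_protospacer_taxon <- function(target_label, origin,
                                       host_label = NULL) {
  if (origin %in% c("phage", "plasmid")) {
    if (is.null(host_label))
      return(taxonomy_label("none", "", "no_hits"))
    return(host_label)
  }
  target_label
}

#' Compare a flank-based and a protospacer-based taxonomy label
#'
#' @param a,b `taxonomy_label`s.
#' @return one of `"concordant_at_phylum"`, `"refines"`, `"conflicts"`,
#'   `"incomparable"`.
#' @export
compare_labels <- function(a, b) {
  if (a$rank == "none" || b$rank == "none") return("incomparable")
  nonspec <- c(a = a$rank == "domain_nonspecific",
               b = b$rank == "domain_nonspecific")
  if (xor(nonspec["a"], nonspec["b"])) return("refines")
  if (all(nonspec)) return("concordant_at_phylum")
  pa <- if (a$rank == "phylum") a$name else a$lineage[["phylum"]]
  pb <- if (b$rank == "phylum") b$name else b$lineage[["phylum"]]
  if (is.na(pa) || is.na(pb)) return("incomparable")
  if (pa == pb) "concordant_at_phylum" else "conflicts"
}

#' Read a ranked taxonomy hit table
#'
#' TSV with columns `contig_id`, `rank_index`, `score`, `phylum`, `class`,
#' `family`, `genus`, `origin`, `host` (empty strings become `NA`).
#'
#' @param path file path.
#' @return data.frame, one row per hit.
#' @export
read_taxon_hits_tsv <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("contig_id", "rank_index", "score", "phylum", "origin")
  if (!all(need %in% names(x)))
    stop("taxonomy hit TSV must have columns: ", paste(need, collapse = ", "))
  for (cc in c("class", "family", "genus", "host"))
    if (is.null(x[[cc]])) x[[cc]] <- NA_character_
  x
}
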