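# Synthetic multi-individual metagenome generator. Every pipeline stage is
# exercised against the ground-truth manifest these functions emit, so the
# whole analysis is testable without any external assembly.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_positions <- function(seq, k) {
  if (k == 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(ch), k)
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

#' Simulation configuration
#'
#' Defaults describe a small but realistic gut-like community: repeat lengths
#' 24-48 nt, spacer lengths 25-70 nt, planted protospacers at Hamming
#' distance 0-6 from their spacers (so both sides of the 4-mismatch
#' reliability threshold occur), a modest cross-individual sharing rate, and
#' leader-proximal placement bias of targeting spacers.
#'
#' @param n_individuals number of individual metagenomes.
#' @param contigs_per_individual background (bacterial) contigs each.
#' @param contig_length_range integer pair, nt.
#' @param n_cassettes arrays planted (at most one per contig).
#' @param repeat_length_range direct-repeat length bounds, nt.
#' @param spacer_length_range spacer length bounds, nt.
#' @param spacers_per_cassette_range spacers per array.
#' @param n_phage_contigs phage/plasmid-like contigs carrying protospacers
#'   (never cassettes).
#' @param n_protospacers planted spacer-to-phage targeting events.
#' @param planted_protospacer_mismatch_distribution weights over Hamming
#'   distances 0..6; must sum to 1.
#' @param sharing_rate fraction of spacers whose sequence is copied into a
#'   cassette of another individual.
#' @param leader_bias >= 0; targeting-spacer serials are drawn with
#'   probability proportional to `exp(-leader_bias * serial)` (0 = uniform).
#' @param cas_adjacent_fraction fraction of cassettes flanked by a cas gene
#'   within 500 nt of the leader end.
#' @param n_decoys tandem-repeat / low-complexity decoy regions to plant.
#' @param seed integer RNG seed; identical config + seed gives byte-identical
#'   output.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_individuals = 5,
                              contigs_per_individual = 4,
                              contig_length_range = c(4000, 8000),
                              n_cassettes = 10,
                              repeat_length_range = c(24, 48),
                              spacer_length_range = c(25, 70),
                              spacers_per_cassette_range = c(6, 12),
                              n_phage_contigs = 5,
                              n_protospacers = 30,
                              planted_protospacer_mismatch_distribution =
                                c(0.30, 0.20, 0.15, 0.15, 0.10, 0.05, 0.05),
                              sharing_rate = 0.10,
                              leader_bias = 0.5,
                              cas_adjacent_fraction = 0.5,
                              n_decoys = 0,
                              seed = 1L) {
  cfg <- as.list(environment())
  w <- cfg$planted_protospacer_mismatch_distribution
  if (length(w) != 7 || abs(sum(w) - 1) > 1e-8 || any(w < 0))
    stop("mismatch distribution must be 7 non-negative weights over 0..6 summing to 1")
  rng <- function(r) length(r) == 2 && r[1] <= r[2] && r[1] > 0
  if (!rng(cfg$contig_length_range) || !rng(cfg$repeat_length_range) ||
      !rng(cfg$spacer_length_range) || !rng(cfg$spacers_per_cassette_range))
    stop("invalid range in simulation config")
  if (cfg$leader_bias < 0) stop("leader_bias must be >= 0")
  structure(cfg, class = "simulation_config")
}

runif_int <- function(n, r) r[1] + floor(stats::runif(n) * (r[2] - r[1] + 1L))

#' Generate a synthetic community with ground truth
#'
#' Background sequence is i.i.d. uniform over ACGT, so chance full-length
#' matches at spacer lengths >= 25 nt are negligible. Each cassette is
#' `repeat (spacer repeat) x n` embedded with non-cassette flanks of at least
#' 150 nt on both sides; half of the cassettes (at random) are embedded
#' reverse-complemented so that the leader end is the right contig end.
#' Targeting spacers are planted as protospacers in phage contigs of the same
#' individual with serial numbers drawn proportional to
#' `exp(-leader_bias * serial)`; `sharing_rate` of spacer sequences are
#' copied into cassettes of other individuals.
#'
#' @param config a [simulation_config()].
#' @return list with elements `contigs` (contig table), `cas` (cas gene
#'   annotations, 0-based half-open), `truth` (manifest: `cassettes`,
#'   `repeats`, `spacers`, `protospacers`, `shared`, `cas`, `decoys`) and
#'   `config`.
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  inds <- sprintf("IND%02d", seq_len(config$n_individuals))

  # --- cassette plans (sequences first, so sharing can rewrite them) -------
  n_bg <- config$n_individuals * config$contigs_per_individual
  if (config$n_cassettes > n_bg)
    stop("infeasible config: more cassettes than background contigs")
  plans <- vector("list", config$n_cassettes)
  for (i in seq_len(config$n_cassettes)) {
    rep_len <- runif_int(1, config$repeat_length_range)
    n_sp <- runif_int(1, config$spacers_per_cassette_range)
    plans[[i]] <- list(
      cassette_id = sprintf("CAS%03d", i),
      repeat_seq = random_dna(rep_len),
      spacer_seqs = vapply(runif_int(n_sp, config$spacer_length_range),
                           random_dna, ""),
      leader_end = if (stats::runif(1) < 0.5) "left" else "right")
  }

  # --- cross-individual sharing -------------------------------------------
  # cassette -> individual assignment (background contig owners, below)
  bg_owner <- rep(inds, each = config$contigs_per_individual)
  host_idx <- sample(n_bg, config$n_cassettes) # one cassette per contig max
  cass_ind <- bg_owner[host_idx]
  total_sp <- sum(vapply(plans, function(p) length(p$spacer_seqs), 0L))
  n_share <- round(config$sharing_rate * total_sp)
  shared <- list()
  if (n_share > 0 && length(unique(cass_ind)) > 1) {
    all_slots <- do.call(rbind, lapply(seq_along(plans), function(i)
      data.frame(cassette = i, serial = seq_along(plans[[i]]$spacer_seqs))))
    donors <- all_slots[sample(nrow(all_slots), min(n_share, nrow(all_slots))), ]
    for (d in seq_len(nrow(donors))) {
      di <- donors$cassette[d]
      cand <- which(cass_ind != cass_ind[di])
      if (!length(cand)) next
      ri <- if (length(cand) == 1) cand else sample(cand, 1)
      rs <- sample(length(plans[[ri]]$spacer_seqs), 1)
      seqd <- plans[[di]]$spacer_seqs[donors$serial[d]]
      plans[[ri]]$spacer_seqs[rs] <- seqd
      shared[[length(shared) + 1]] <- data.frame(
        sequence = seqd,
        donor_cassette = plans[[di]]$cassette_id, donor_serial = donors$serial[d],
        recipient_cassette = plans[[ri]]$cassette_id, recipient_serial = rs,
        stringsAsFactors = FALSE)
    }
  }
  shared <- if (length(shared)) do.call(rbind, shared) else
    data.frame(sequence = character(0), donor_cassette = character(0),
               donor_serial = integer(0), recipient_cassette = character(0),
               recipient_serial = integer(0))

  # --- assemble background contigs with embedded cassettes ----------------
  min_flank <- 150L
  contig_rows <- list(); truth_cas <- list(); truth_rep <- list()
  truth_spc <- list(); cas_rows <- list()
  cas_flagged <- stats::runif(config$n_cassettes) < config$cas_adjacent_fraction
  k_cas <- 0L
  for (b in seq_len(n_bg)) {
    ind <- bg_owner[b]
    cid <- sprintf("%s_C%02d", ind, ((b - 1L) %% config$contigs_per_individual) + 1L)
    len <- runif_int(1, config$contig_length_range)
    seq <- random_dna(len)
    ci <- which(host_idx == b)
    if (length(ci) == 1) {
      p <- plans[[ci]]
      n_sp <- length(p$spacer_seqs)
      body <- paste0(p$repeat_seq,
                     paste0(p$spacer_seqs, p$repeat_seq, collapse = ""))
      body_len <- nchar(body)
      if (body_len + 2L * min_flank > len)
        stop("infeasible config: cassette longer than contig")
      # leader->trailer coordinates within the body
      rep_len <- nchar(p$repeat_seq)
      sp_starts <- cumsum(c(rep_len, head(nchar(p$spacer_seqs) + rep_len, -1)))
      sp_ends <- sp_starts + nchar(p$spacer_seqs)
      rp_starts <- c(0L, sp_ends)
      rp_ends <- rp_starts + rep_len
      emb <- if (p$leader_end == "left") body else revcomp(body)
      off <- min_flank + floor(stats::runif(1) * (len - body_len - 2L * min_flank + 1L))
      seq <- paste0(substr(seq, 1, off), emb,
                    substr(seq, off + body_len + 1L, len))
      if (p$leader_end == "left") {
        sp_s <- off + sp_starts; sp_e <- off + sp_ends
        rp_s <- off + rp_starts; rp_e <- off + rp_ends
        sp_seq_plus <- p$spacer_seqs
      } else {
        sp_s <- off + body_len - sp_ends; sp_e <- off + body_len - sp_starts
        rp_s <- off + body_len - rp_ends; rp_e <- off + body_len - rp_starts
        sp_seq_plus <- revcomp(p$spacer_seqs)
      }
      truth_cas[[length(truth_cas) + 1]] <- data.frame(
        cassette_id = p$cassette_id, contig_id = cid, individual_id = ind,
        start = off, end = off + body_len, leader_end = p$leader_end,
        n_spacers = n_sp, repeat_seq = p$repeat_seq, stringsAsFactors = FALSE)
      truth_rep[[length(truth_rep) + 1]] <- data.frame(
        cassette_id = p$cassette_id, contig_id = cid,
        start = sort(rp_s), end = sort(rp_e), stringsAsFactors = FALSE)
      truth_spc[[length(truth_spc) + 1]] <- data.frame(
        cassette_id = p$cassette_id, contig_id = cid, individual_id = ind,
        serial = seq_len(n_sp), start = sp_s, end = sp_e,
        sequence = sp_seq_plus, leader_seq = p$spacer_seqs,
        stringsAsFactors = FALSE)
      if (cas_flagged[ci]) {
        k_cas <- k_cas + 1L
        gene <- sample(c("cas1", "cas3", "cas9", "cas10"), 1,
                       prob = c(0.4, 0.25, 0.2, 0.15))
        glen <- 600L + runif_int(1, c(0, 300))
        gap <- runif_int(1, c(10, 120))
        if (p$leader_end == "left") {
          ge <- max(1L, off - gap); gs <- max(0L, ge - glen)
          strand <- "+"
        } else {
          gs <- min(len - 1L, off + body_len + gap); ge <- min(len, gs + glen)
          strand <- "-"
        }
        if (ge > gs)
          cas_rows[[k_cas]] <- data.frame(
            contig_id = cid, gene = gene, start = gs, end = ge,
            strand = strand, cassette_id = p$cassette_id,
            stringsAsFactors = FALSE)
      }
    }
    contig_rows[[b]] <- data.frame(
      contig_id = cid, individual_id = ind, dataset = "SYN",
      sequence = seq, length = nchar(seq), stringsAsFactors = FALSE)
  }

  # --- phage contigs and planted protospacers -----------------------------
  phage_owner <- inds[((seq_len(config$n_phage_contigs) - 1L) %%
                         config$n_individuals) + 1L]
  phage <- lapply(seq_len(config$n_phage_contigs), function(i) {
    len <- runif_int(1, config$contig_length_range)
    data.frame(contig_id = sprintf("%s_P%02d", phage_owner[i], i),
               individual_id = phage_owner[i], dataset = "SYN",
               sequence = random_dna(len), length = len,
               stringsAsFactors = FALSE)
  })
  phage <- do.call(rbind, phage)
  spc_all <- if (length(truth_spc)) do.call(rbind, truth_spc) else NULL
  cas_all <- if (length(truth_cas)) do.call(rbind, truth_cas) else NULL
  occupied <- lapply(seq_len(nrow(phage)), function(i) integer(0))
  names(occupied) <- phage$contig_id
  truth_pro <- list()
  if (config$n_protospacers > 0 && !is.null(cas_all)) {
    eligible_cas <- which(cas_all$individual_id %in% phage$individual_id)
    if (!length(eligible_cas))
      stop("infeasible config: no cassette shares an individual with a phage contig")
    for (e in seq_len(config$n_protospacers)) {
      ci <- if (length(eligible_cas) == 1) eligible_cas else sample(eligible_cas, 1)
      crow <- cas_all[ci, ]
      n_sp <- crow$n_spacers
      wts <- exp(-config$leader_bias * seq_len(n_sp))
      serial <- sample.int(n_sp, 1, prob = wts)
      sp <- spc_all[spc_all$cassette_id == crow$cassette_id &
                      spc_all$serial == serial, ]
      h <- sample(0:6, 1, prob = config$planted_protospacer_mismatch_distribution)
      proto <- mutate_positions(sp$sequence, min(h, nchar(sp$sequence)))
      strand <- if (stats::runif(1) < 0.5) "+" else "-"
      pcand <- which(phage$individual_id == crow$individual_id)
      pi <- if (length(pcand) == 1) pcand else sample(pcand, 1)
      plen <- phage$length[pi]; L <- nchar(proto)
      # find a slot that does not touch previously planted protospacers
      ok <- FALSE
      for (try in 1:50) {
        s <- floor(stats::runif(1) * (plen - L + 1L))
        span <- (s + 1L):(s + L)
        if (!any(span %in% occupied[[phage$contig_id[pi]]])) { ok <- TRUE; break }
      }
      if (!ok) next
      occupied[[phage$contig_id[pi]]] <- c(occupied[[phage$contig_id[pi]]], span)
      ins <- if (strand == "+") proto else revcomp(proto)
      phage$sequence[pi] <- paste0(substr(phage$sequence[pi], 1, s), ins,
                                   substr(phage$sequence[pi], s + L + 1L, plen))
      truth_pro[[length(truth_pro) + 1]] <- data.frame(
        cassette_id = crow$cassette_id, serial = serial,
        spacer_contig = sp$contig_id, individual_id = crow$individual_id,
        target_contig = phage$contig_id[pi], start = s, end = s + L,
        strand = strand, mismatches = min(h, L), stringsAsFactors = FALSE)
    }
  }
  phage$length <- nchar(phage$sequence)
  contigs <- rbind(do.call(rbind, contig_rows), phage)
  rownames(contigs) <- NULL
  cas <- if (length(cas_rows)) do.call(rbind, cas_rows) else
    data.frame(contig_id = character(0), gene = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               cassette_id = character(0))
  truth <- list(
    cassettes = cas_all %||% data.frame(),
    repeats = if (length(truth_rep)) do.call(rbind, truth_rep) else data.frame(),
    spacers = spc_all %||% data.frame(),
    protospacers = if (length(truth_pro)) do.call(rbind, truth_pro) else
      data.frame(cassette_id = character(0), serial = integer(0),
                 spacer_contig = character(0), individual_id = character(0),
                 target_contig = character(0), start = integer(0),
                 end = integer(0), strand = character(0), mismatches = integer(0)),
    shared = shared,
    cas = cas,
    decoys = data.frame(decoy_id = character(0), contig_id = character(0),
                        start = integer(0), end = integer(0),
                        unit_length = integer(0), n_copies = integer(0),
                        kind = character(0)))
  out <- list(contigs = contigs, cas = cas, truth = truth, config = config)
  if (config$n_decoys > 0)
    out <- plant_decoys(out, config$n_decoys, seed = config$seed + 1L)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ground-truth spacer flags for a synthetic community
#'
#' Convenience accessor over the truth manifest: the spacer table with a
#' `targeting` column (planted protospacer events) plus an eligibility table
#' for the position test (all planted cassettes are complete by
#' construction, with the planted leader end).
#'
#' @param community output of [generate_community()].
#' @return list `spacers` (truth spacers with `targeting`) and `cassettes`
#'   (`cassette_id`, `complete`, `leader_end`).
#' @export
truth_spacer_flags <- function(community) {
  sp <- community$truth$spacers
  key <- paste(sp$cassette_id, sp$serial)
  tkey <- unique(paste(community$truth$protospacers$cassette_id,
                       community$truth$protospacers$serial))
  sp$targeting <- key %in% tkey
  sp$canonical <- canonical_seq(sp$leader_seq)
  list(spacers = sp,
       cassettes = data.frame(
         cassette_id = community$truth$cassettes$cassette_id,
         complete = TRUE,
         leader_end = community$truth$cassettes$leader_end,
         stringsAsFactors = FALSE))
}

#' Plant decoy repeat regions
#'
#' Inserts tandem-repeat and low-complexity regions (the classic false
#' positives of k-mer based array detectors) into cassette-free background
#' contigs and records them in the truth manifest as negative examples for
#' the consensus filter.
#'
#' @param community output of [generate_community()].
#' @param n_decoys number of decoy regions.
#' @param seed RNG seed.
#' @return the community with updated contigs and `truth$decoys`.
#' @export
plant_decoys <- function(community, n_decoys, seed = 1L) {
  if (n_decoys == 0) return(community)
  set.seed(seed)
  contigs <- community$contigs
  used <- unique(c(community$truth$cassettes$contig_id,
                   community$truth$decoys$contig_id))
  free <- which(!(contigs$contig_id %in% used) &
                  !grepl("_P", contigs$contig_id, fixed = TRUE))
  if (length(free) < n_decoys)
    stop("not enough cassette-free background contigs for decoys")
  slots <- free[sample(length(free), n_decoys)]
  rows <- list()
  for (d in seq_len(n_decoys)) {
    i <- slots[d]
    kind <- if (stats::runif(1) < 0.5) "tandem" else "low_complexity"
    if (kind == "tandem") {
      ulen <- runif_int(1, c(8, 14)); ncp <- runif_int(1, c(8, 16))
      unit <- random_dna(ulen)
      region <- strrep(unit, ncp)
    } else {
      ulen <- 2L; ncp <- 60L
      unit <- paste0(sample(c("A", "T"), 2, replace = TRUE), collapse = "")
      region <- strrep(unit, ncp)
    }
    rl <- nchar(region); len <- contigs$length[i]
    s <- 200L + floor(stats::runif(1) * (len - rl - 400L))
    contigs$sequence[i] <- paste0(substr(contigs$sequence[i], 1, s), region,
                                  substr(contigs$sequence[i], s + rl + 1L, len))
    rows[[d]] <- data.frame(
      decoy_id = sprintf("DEC%03d", nrow(community$truth$decoys) + d),
      contig_id = contigs$contig_id[i], start = s, end = s + rl,
      unit_length = ulen, n_copies = ncp, kind = kind,
      stringsAsFactors = FALSE)
  }
  community$contigs <- contigs
  community$truth$decoys <- rbind(community$truth$decoys, do.call(rbind, rows))
  community
}

#' Simulate per-program detector reports
#'
#' For each planted cassette, each simulated program (CRT, CFI, PIL)
#' independently reports the array with probability `1 - fn_rates[program]`,
#' with all repeat boundaries shifted by one uniform offset in
#' `[-jitter, jitter]` nt. Decoy regions are reported with per-program
#' probabilities `decoy_rates` (CRT and PILER-like detectors are prone to
#' tandem repeats and low-complexity sequence; a CRISPRFinder-like detector
#' much less so).
#'
#' @param community output of [generate_community()].
#' @param fn_rates named false-negative rates for CRT, CFI, PIL.
#' @param jitter max absolute boundary shift, nt.
#' @param seed RNG seed.
#' @param decoy_rates named per-program decoy report probabilities.
#' @return prediction table in the [ingest_predictions_tsv()] schema.
#' @export
emit_detector_predictions <- function(community,
                                      fn_rates = c(CRT = 0, CFI = 0, PIL = 0),
                                      jitter = 0L, seed = 1L,
                                      decoy_rates = c(CRT = 0.8, CFI = 0.1,
                                                      PIL = 0.8)) {
  set.seed(seed)
  progs <- c("CRT", "CFI", "PIL")
  stopifnot(all(progs %in% names(fn_rates)))
  rows <- list()
  tc <- community$truth$cassettes
  tr <- community$truth$repeats
  for (i in seq_len(nrow(tc))) {
    reps <- tr[tr$cassette_id == tc$cassette_id[i], ]
    clen <- community$contigs$length[
      match(tc$contig_id[i], community$contigs$contig_id)]
    for (pg in progs) {
      if (stats::runif(1) < fn_rates[[pg]]) next
      off <- if (jitter > 0) runif_int(1, c(-jitter, jitter)) else 0L
      s <- reps$start + off; e <- reps$end + off
      shift <- max(0L - min(s), max(e) - clen, 0L)
      if (min(s) < 0) { s <- s + shift; e <- e + shift }
      if (max(e) > clen) { s <- s - shift; e <- e - shift }
      rows[[length(rows) + 1]] <- data.frame(
        prediction_id = paste(tc$contig_id[i], pg, tc$cassette_id[i], sep = "/"),
        contig_id = tc$contig_id[i], program = pg, start = s, end = e,
        consensus = tc$repeat_seq[i], stringsAsFactors = FALSE)
    }
  }
  dd <- community$truth$decoys
  for (i in seq_len(nrow(dd))) {
    # detectors mis-segment tandem arrays into alternating "repeat"/"spacer"
    # copies, so every second unit is reported as a repeat
    ncp <- max(2L, min(dd$n_copies[i] %/% 2L, 8L))
    s <- dd$start[i] + (seq_len(ncp) - 1L) * 2L * dd$unit_length[i]
    e <- s + dd$unit_length[i]
    unit <- substr0(community$contigs$sequence[
      match(dd$contig_id[i], community$contigs$contig_id)],
      dd$start[i], dd$start[i] + dd$unit_length[i])
    for (pg in progs) {
      if (stats::runif(1) >= decoy_rates[[pg]]) next
      rows[[length(rows) + 1]] <- data.frame(
        prediction_id = paste(dd$contig_id[i], pg, dd$decoy_id[i], sep = "/"),
        contig_id = dd$contig_id[i], program = pg, start = s, end = e,
        consensus = unit, stringsAsFactors = FALSE)
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
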