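# Kozak consensus used by the generator: positions -5..-1 then +4..+6.
# Base-balanced (each nucleotide twice) so the pooled background of trained
# models stays near uniform and position weights stay comparable.
.KOZAK_CONSENSUS <- c("C", "A", "A", "T", "C", "G", "G", "T")

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. Defaults describe
#' one embryonic-style study: three stages x two replicas, footprint lengths
#' 26-36 nt peaking at 32, a per-length dominant-frame map (26-30 nt ->
#' frame 0, 31 nt -> a mix of frames 0 and 2, 32-36 nt -> frame 2), framing
#' fidelity 0.75, and a library size of 4e7 mapped reads per sample (the
#' recommended minimal depth of ~40 million mapped reads per replica for
#' lncRNA work). Planted RPKM levels sit an order of magnitude above the
#' RPKM > 1 classification threshold for expressed classes and an order of
#' magnitude below it for silent ones.
#'
#' @param seed Integer master seed; every emitted file is a pure function of
#'   (config, seed).
#' @param n_lncrnas,n_canonical Number of lncRNA and canonical transcripts.
#' @param orfs_per_transcript Integer range (min, max) of planted ORFs per
#'   lncRNA.
#' @param orf_codons,canonical_codons Codon-count ranges for planted lncORFs
#'   and canonical ORFs (stop excluded).
#' @param status_mix Named fractions (`robust`, `limited`, `ribo_bound`,
#'   `transcribed_only`) over ORFs of transcribed lncRNAs; must sum to 1.
#'   Allocation is exact by construction (largest-remainder rounding).
#' @param frac_untranscribed Fraction of lncRNAs with no transcription
#'   (their ORFs are planted `not_expressed`).
#' @param rpf_lengths,rpf_length_probs RPF length support and distribution.
#' @param frame_offset_map Named integer vector over `rpf_lengths`: dominant
#'   frame per length; `NA` marks a mixed length (frames 0/2 with equal
#'   probability).
#' @param framing_fidelity Probability pi that a footprint of a translated
#'   ORF falls in the length's dominant frame; the other two frames share
#'   the remainder equally, so pi = 1/3 means uniform frames (>= 1/3).
#' @param rna_rpkm,fp_rpkm Planted RPKM of transcribed lncRNAs / bound
#'   lncORFs.
#' @param rna_rpkm_low,fp_rpkm_low Planted RPKM of silent transcripts /
#'   unbound ORFs.
#' @param canonical_rna_rpkm,canonical_fp_rpkm Planted canonical levels.
#' @param library_size Total mapped reads per sample (RPKM denominator).
#' @param stages,replicas Sample structure to emit.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_lncrnas = 60, n_canonical = 30,
                       orfs_per_transcript = c(1, 6),
                       orf_codons = c(15, 60),
                       canonical_codons = c(80, 150),
                       status_mix = c(robust = 0.15, limited = 0.15,
                                      ribo_bound = 0.20,
                                      transcribed_only = 0.50),
                       frac_untranscribed = 0.15,
                       rpf_lengths = 26:36,
                       rpf_length_probs = c(1, 2, 4, 7, 10, 14, 20, 14,
                                            8, 4, 2) / 86,
                       frame_offset_map = stats::setNames(
                         c(0L, 0L, 0L, 0L, 0L, NA, 2L, 2L, 2L, 2L, 2L),
                         26:36),
                       framing_fidelity = 0.75,
                       rna_rpkm = 10, fp_rpkm = 30,
                       rna_rpkm_low = 0.2, fp_rpkm_low = 0.1,
                       canonical_rna_rpkm = 30, canonical_fp_rpkm = 60,
                       library_size = 4e7,
                       stages = c("Early", "Mid", "Late"),
                       replicas = c("T", "B")) {
  stopifnot(abs(sum(status_mix) - 1) < 1e-9,
            framing_fidelity >= 1/3, framing_fidelity <= 1,
            length(rpf_lengths) == length(rpf_length_probs),
            length(frame_offset_map) == length(rpf_lengths))
  structure(as.list(environment()), class = "sim_config")
}

# Largest-remainder allocation so planted class counts are exact.
.allocate_exact <- function(n, fractions) {
  raw <- n * fractions
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  counts
}

# Sample one 8-mer start context carrying a planted strength: round(8*s)
# positions take the consensus base, the rest draw uniformly from the other
# three, so strength is a property of the emitted sequence itself.
.sample_context <- function(strength) {
  k <- round(8 * strength)
  cons_at <- if (k > 0) sample.int(8, k) else integer(0)
  ctx <- character(8)
  for (j in 1:8) {
    ctx[j] <- if (j %in% cons_at) .KOZAK_CONSENSUS[j] else
      sample(setdiff(c("A", "C", "G", "T"), .KOZAK_CONSENSUS[j]), 1)
  }
  ctx
}

# G-free sense codons (no stop, no ATG possible anywhere downstream).
.safe_codons <- function() {
  bases <- c("A", "C", "T")
  cods <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(cods, "TAA")
}

# Assemble one transcript with n planted non-overlapping AUG->STOP ORFs.
# Only planted starts (and possibly in-frame internal AUGs sharing the
# planted stop, which the caller's 5'-most rule collapses) can spell ATG.
.build_transcript <- function(n_orfs, codon_range, strengths) {
  safe <- .safe_codons()
  parts <- character(0)
  pos <- 0L
  starts <- ends <- n_codons <- integer(n_orfs)
  contexts <- character(n_orfs)
  for (i in seq_len(n_orfs)) {
    spacer_len <- sample(15:40, 1)
    prefix <- paste(sample(c("A", "C", "T"), spacer_len - 5, TRUE),
                    collapse = "")
    repeat {
      ctx <- .sample_context(strengths[i])
      five <- paste(ctx[1:5], collapse = "")
      codon2 <- paste(ctx[6:8], collapse = "")
      if (codon2 %in% .STOP_CODONS || codon2 == "ATG") next
      window <- paste0(substr(prefix, max(1, nchar(prefix) - 1),
                              nchar(prefix)), five, "ATG")
      hits <- gregexpr("ATG", window, fixed = TRUE)[[1]]
      if (length(hits) == 1 && hits[1] == nchar(window) - 2) break
    }
    nc <- sample(codon_range[1]:codon_range[2], 1)
    interior <- paste(sample(safe, nc - 2, TRUE), collapse = "")
    orf_nt <- paste0("ATG", codon2, interior, "TAA")
    parts <- c(parts, prefix, five, orf_nt)
    starts[i] <- pos + spacer_len
    ends[i] <- starts[i] + 3L * (nc + 1L)
    n_codons[i] <- nc
    contexts[i] <- paste(ctx, collapse = "")
    pos <- ends[i]
  }
  tail <- paste(sample(c("A", "C", "T"), sample(15:40, 1), TRUE),
                collapse = "")
  list(seq = paste(c(parts, tail), collapse = ""),
       start = starts, end = ends, n_codons = n_codons, contexts = contexts)
}

#' Simulate a transcriptome with planted ORF-level ground truth
#'
#' Generates lncRNA transcripts carrying non-overlapping AUG->STOP ORFs with
#' planted translation statuses and Kozak strengths, plus canonical
#' transcripts (one long, robustly translated ORF each) used downstream for
#' frame calibration, Kozak-model training and MILC reference usage. The
#' construction guarantees that [find_orfs()] on the emitted sequences
#' recovers exactly the planted ORF catalogue. Deterministic given the
#' config seed.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_data`: `transcripts` ([transcript_set()]),
#'   `orfs` (planted lncORF catalogue, [find_orfs()] schema plus
#'   `cistronic_rank`), `canonical` (canonical ORF catalogue), `truth`
#'   (per-lncORF planted status, framed replica for limited ORFs, Kozak
#'   strength and context), `config`.
#' @export
simulate_transcriptome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  max_len <- 40 + (cfg$orf_codons[2] + 1) * 3 + 45
  if (max_len * cfg$orfs_per_transcript[2] > 1e5)
    stop("simulate_transcriptome: infeasible ORF packing")

  seqs <- character(0)
  lnc_rows <- list()
  n_untx <- round(cfg$frac_untranscribed * cfg$n_lncrnas)
  untranscribed <- rep(c(TRUE, FALSE),
                       c(n_untx, cfg$n_lncrnas - n_untx))[
                         sample.int(cfg$n_lncrnas)]
  for (i in seq_len(cfg$n_lncrnas)) {
    tx <- sprintf("lnc%03d", i)
    n_orfs <- sample(cfg$orfs_per_transcript[1]:cfg$orfs_per_transcript[2], 1)
    strengths <- stats::runif(n_orfs)
    bt <- .build_transcript(n_orfs, cfg$orf_codons, strengths)
    seqs[tx] <- bt$seq
    lnc_rows[[i]] <- data.frame(
      transcript = tx, start = bt$start, end = bt$end,
      n_codons = bt$n_codons, kozak_strength = strengths,
      kozak_context = bt$contexts, cistronic_rank = seq_len(n_orfs),
      transcribed = !untranscribed[i], stringsAsFactors = FALSE)
  }
  lnc <- do.call(rbind, lnc_rows)
  lnc$orf_id <- paste(lnc$transcript, lnc$start, lnc$end, sep = "_")

  # exact status allocation over ORFs of transcribed lncRNAs
  lnc$status <- "not_expressed"
  idx_tx <- which(lnc$transcribed)
  counts <- .allocate_exact(length(idx_tx), cfg$status_mix)
  labels <- rep(names(counts), counts)
  lnc$status[idx_tx] <- labels[sample.int(length(idx_tx))]
  lnc$framed_replica <- NA_character_
  lim <- lnc$status == "limited"
  lnc$framed_replica[lim] <- sample(cfg$replicas, sum(lim), TRUE)

  can_rows <- list()
  for (i in seq_len(cfg$n_canonical)) {
    tx <- sprintf("can%03d", i)
    strength <- stats::runif(1, 0.7, 1)
    bt <- .build_transcript(1, cfg$canonical_codons, strength)
    seqs[tx] <- bt$seq
    can_rows[[i]] <- data.frame(
      transcript = tx, start = bt$start, end = bt$end,
      n_codons = bt$n_codons, kozak_strength = strength,
      kozak_context = bt$contexts, cistronic_rank = 1L,
      stringsAsFactors = FALSE)
  }
  can <- do.call(rbind, can_rows)
  can$orf_id <- paste(can$transcript, can$start, can$end, sep = "_")

  add_seq <- function(df) {
    df$nt_seq <- substring(seqs[df$transcript], df$start + 1L, df$end)
    df$peptide <- vapply(df$nt_seq, translate_nt, character(1),
                         USE.NAMES = FALSE)
    df$strand <- "+"
    df
  }
  lnc <- add_seq(lnc)
  can <- add_seq(can)

  cols <- c("orf_id", "transcript", "start", "end", "strand", "n_codons",
            "nt_seq", "peptide", "cistronic_rank")
  truth <- lnc[c("orf_id", "transcript", "status", "framed_replica",
                 "kozak_strength", "kozak_context", "cistronic_rank",
                 "transcribed", "n_codons")]
  rownames(truth) <- rownames(lnc) <- rownames(can) <- NULL
  structure(list(transcripts = transcript_set(seqs),
                 orfs = lnc[cols], canonical = can[cols],
                 truth = truth, config = cfg),
            class = "sim_data")
}

# Per-sample deterministic seed, derived from the master seed; kept within
# 32-bit integer range.
.sample_seed <- function(config, stage, replica, mode) {
  si <- match(stage, config$stages)
  ri <- match(replica, config$replicas)
  mi <- match(mode, c("ribo", "rna"))
  if (anyNA(c(si, ri, mi)))
    stop("unknown stage/replica/mode for this config")
  (abs(config$seed) %% 1000003L) * 1009L + si * 101L + ri * 13L + mi
}

#' Simulate a sequencing sample as a transcript-aligned read table
#'
#' `ribo` mode emits ribosome-protected fragments: counts per ORF are
#' Poisson around the planted RPKM, footprint lengths follow the configured
#' distribution, and each read's frame equals the length's dominant frame
#' with probability pi (the framing fidelity; planted 1/3 for unframed
#' classes) and is uniform otherwise. Limited ORFs carry framing fidelity in
#' their planted replica only. `rna` mode emits uniform-position 50-nt reads
#' scaled by the transcript's planted expression. Deterministic given
#' (config, stage, replica, mode).
#'
#' @param sim A `sim_data` from [simulate_transcriptome()].
#' @param mode `"ribo"` or `"rna"`.
#' @param stage,replica Sample coordinates (must match the config).
#' @return A [read_table()].
#' @export
simulate_reads <- function(sim, mode = c("ribo", "rna"), stage, replica) {
  stopifnot(inherits(sim, "sim_data"))
  mode <- match.arg(mode)
  cfg <- sim$config
  set.seed(.sample_seed(cfg, stage, replica, mode))
  lib_m <- cfg$library_size / 1e6
  rows <- list()
  if (mode == "ribo") {
    orfs <- rbind(
      cbind(sim$orfs[c("orf_id", "transcript", "start", "end", "n_codons")],
            status = sim$truth$status,
            framed_replica = sim$truth$framed_replica),
      cbind(sim$canonical[c("orf_id", "transcript", "start", "end",
                            "n_codons")],
            status = "canonical", framed_replica = NA_character_))
    for (i in seq_len(nrow(orfs))) {
      st <- orfs$status[i]
      fp <- switch(st,
                   canonical = cfg$canonical_fp_rpkm,
                   robust = , limited = , ribo_bound = cfg$fp_rpkm,
                   transcribed_only = , not_expressed = cfg$fp_rpkm_low)
      pi_fr <- switch(st,
                      canonical = , robust = cfg$framing_fidelity,
                      limited = if (identical(orfs$framed_replica[i], replica))
                        cfg$framing_fidelity else 1/3,
                      1/3)
      len_nt <- 3 * (orfs$n_codons[i] + 1)
      n <- stats::rpois(1, fp * (len_nt / 1000) * lib_m)
      if (n == 0) next
      L <- sample(cfg$rpf_lengths, n, TRUE, prob = cfg$rpf_length_probs)
      dom <- cfg$frame_offset_map[as.character(L)]
      dom[is.na(dom)] <- sample(c(0L, 2L), sum(is.na(dom)), TRUE)
      # dominant frame with probability exactly pi, the other two frames
      # equally likely otherwise (pi = 1/3 gives uniform frames)
      alt <- (dom + sample(1:2, n, TRUE)) %% 3L
      frame <- ifelse(stats::runif(n) < pi_fr, dom, alt)
      u <- sample.int(orfs$n_codons[i], n, TRUE) - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        transcript = orfs$transcript[i],
        pos5 = orfs$start[i] + 3L * u + frame,
        length = L, stringsAsFactors = FALSE)
    }
  } else {
    txs <- names(sim$transcripts)
    rate <- stats::setNames(rep(cfg$rna_rpkm_low, length(txs)), txs)
    rate[sim$truth$transcript[sim$truth$transcribed]] <- cfg$rna_rpkm
    rate[grep("^can", txs)] <- cfg$canonical_rna_rpkm
    for (tx in txs) {
      len <- nchar(sim$transcripts[[tx]])
      n <- stats::rpois(1, rate[tx] * (len / 1000) * lib_m)
      if (n == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        transcript = tx, pos5 = sample.int(len, n, TRUE) - 1L,
        length = 50L, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    df <- data.frame(transcript = character(0), pos5 = integer(0),
                     length = integer(0), count = integer(0))
    return(read_table(df, cfg$library_size))
  }
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(list(count = rep(1L, nrow(df))),
                          df[c("transcript", "pos5", "length")], FUN = sum)
  agg <- agg[order(agg$transcript, agg$pos5, agg$length), ]
  rownames(agg) <- NULL
  read_table(agg, cfg$library_size)
}

# Substitution bookkeeping for the codon evolver: for every sense codon the
# nine single-nucleotide neighbours with transition flag, synonymy and stop
# status.
.codon_moves_env <- new.env(parent = emptyenv())
.codon_moves <- function() {
  if (!is.null(.codon_moves_env$moves)) return(.codon_moves_env$moves)
  gc <- .codon_table()
  moves <- list()
  for (cod in .sense_codons()) {
    ch <- strsplit(cod, NULL)[[1]]
    to <- character(9); ts <- logical(9); syn <- logical(9); stp <- logical(9)
    k <- 0
    for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"), ch[p])) {
      k <- k + 1
      mut <- ch; mut[p] <- b
      mcod <- paste(mut, collapse = "")
      to[k] <- mcod
      ts[k] <- (ch[p] %in% c("A", "G")) == (b %in% c("A", "G"))
      stp[k] <- gc[mcod] == "*"
      syn[k] <- !stp[k] && gc[mcod] == gc[cod]
    }
    moves[[cod]] <- list(to = to, ts = ts, syn = syn, stop = stp)
  }
  .codon_moves_env$moves <- moves
  moves
}

#' Evolve a coding sequence under a codon substitution model
#'
#' Continuous-time (Gillespie) simulation of single-nucleotide substitutions
#' on a codon sequence: transitions are `kappa` times faster than
#' transversions, nonsynonymous changes are scaled by `omega`, and
#' stop-generating changes are rejected (rate 0). Rates are normalised so
#' that `t` is the expected number of substitutions per nucleotide site
#' under neutrality (`omega = 1`).
#'
#' @param nt In-frame coding nucleotide string (sense codons only; a
#'   trailing stop codon, if present, is held fixed).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param t Branch length (neutral expected substitutions per site, >= 0).
#' @param kappa Transition/transversion rate ratio.
#' @param seed Optional integer seed.
#' @return The evolved nucleotide string (same length, stop restored).
#' @export
evolve_codon_sequence <- function(nt, omega, t, kappa = 2, seed = NULL) {
  stopifnot(omega >= 0, t >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- nchar(nt)
  stopifnot(n %% 3 == 0)
  st <- seq(1, n, 3)
  cods <- substring(nt, st, st + 2)
  stop_tail <- character(0)
  if (cods[length(cods)] %in% .STOP_CODONS) {
    stop_tail <- cods[length(cods)]
    cods <- cods[-length(cods)]
  }
  if (any(cods %in% .STOP_CODONS))
    stop("evolve_codon_sequence: internal stop codon")
  moves <- .codon_moves()
  rate_of <- function(cod) {
    m <- moves[[cod]]
    r <- ifelse(m$ts, kappa, 1) / (kappa + 2)
    r[m$stop] <- 0
    r[!m$syn & !m$stop] <- r[!m$syn & !m$stop] * omega
    r
  }
  rates <- lapply(cods, rate_of)
  totals <- vapply(rates, sum, numeric(1))
  time <- 0
  repeat {
    R <- sum(totals)
    if (R <= 0) break
    time <- time + stats::rexp(1, R)
    if (time > t) break
    i <- sample.int(length(cods), 1, prob = totals)
    m <- moves[[cods[i]]]
    j <- sample.int(9, 1, prob = rates[[i]])
    cods[i] <- m$to[j]
    rates[[i]] <- rate_of(cods[i])
    totals[i] <- sum(rates[[i]])
  }
  paste(c(cods, stop_tail), collapse = "")
}

#' Evolve per-species homologue databases with decoys
#'
#' For each input ORF, evolves the coding sequence at the given selection
#' regime and divergence, translates the descendant, and adds
#' composition-matched decoys (residue-shuffled homologue peptides) at
#' `decoys_per_orf` per homologue. Homologues shorter than 10 AA after
#' evolution cannot occur (length is preserved). Deterministic given `seed`.
#'
#' @param orfs ORF data.frame with `orf_id` and `nt_seq` (stop codon
#'   included or not).
#' @param omega,t,kappa Passed to [evolve_codon_sequence()].
#' @param species Species label of the emitted database.
#' @param decoys_per_orf Number of shuffled decoys per homologue.
#' @param seed Integer seed.
#' @return List: `db` (a [smorf_db()] of homologues + decoys), `truth`
#'   (data.frame `query`, `target`), `nt` (named homologue coding
#'   sequences, for codon-alignment/dN-dS use).
#' @export
evolve_homologues <- function(orfs, omega, t, kappa = 2, species = "spX",
                              decoys_per_orf = 10, seed = 1) {
  set.seed(seed)
  peps <- character(0)
  nts <- character(0)
  truth <- data.frame(query = character(0), target = character(0))
  for (i in seq_len(nrow(orfs))) {
    nt <- orfs$nt_seq[i]
    evolved <- evolve_codon_sequence(nt, omega, t, kappa)
    pep <- translate_nt(if (nchar(evolved) %% 3 == 0) evolved else
      stop("bad length"))
    hid <- paste0(species, "_hom_", orfs$orf_id[i])
    peps[hid] <- pep
    nts[hid] <- evolved
    truth <- rbind(truth, data.frame(query = orfs$orf_id[i], target = hid))
    for (d in seq_len(decoys_per_orf)) {
      did <- paste0(species, "_decoy_", orfs$orf_id[i], "_", d)
      peps[did] <- paste(sample(strsplit(pep, NULL)[[1]]), collapse = "")
    }
  }
  list(db = smorf_db(peps, species = species), truth = truth, nt = nts)
}
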