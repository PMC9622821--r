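#' Run the full analysis pipeline on simulated data
#'
#' Orchestrates every stage end to end on a synthetic dataset with planted
#' truth: transcriptome simulation, ORF calling, per-sample frame
#' calibration on canonical ORFs, binomial framing calls, RPKM
#' quantification, the four-state translation-status classifier per stage,
#' stage-specificity summary, TE Z-ratios across time-contiguous stage
#' transitions on the constitutively transcribed set, Kozak model training
#' (canonical contexts) and lncORF scoring, cistronic ranks, MILC against
#' canonical codon usage, Poisson clustering of ribo-bound ORFs per
#' transcript, and optionally the homology search plus dN/dS on evolved
#' homologues. All tables are written as TSV together with a manifest
#' recording every threshold and seed, so a run is reproducible from the
#' manifest alone; a run is idempotent for a fixed config.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if missing). `NULL` keeps
#'   everything in memory.
#' @param alpha Binomial framing-test significance level.
#' @param rpkm_threshold Expression threshold for the classifier.
#' @param te_threshold Z-ratio significance threshold.
#' @param run_homology Also evolve a homologous species database and run the
#'   reciprocal search and dN/dS on robust lncORFs (slower).
#' @param homology_omega,homology_t Selection regime and divergence of the
#'   evolved species when `run_homology` is TRUE.
#' @return List (class `pipeline_result`) of result tables: `orfs`,
#'   `framing`, `expression`, `status`, `stage_summary`, `te_changes`,
#'   `kozak`, `milc`, `clustering`, `truth`, and (optionally) `homology`,
#'   `dnds`; plus `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), outdir = NULL,
                         alpha = 0.01, rpkm_threshold = 1,
                         te_threshold = 1.5, run_homology = FALSE,
                         homology_omega = 0.2, homology_t = 0.15) {
  sim <- simulate_transcriptome(config)
  orfs <- find_orfs(sim$transcripts)
  lnc_orfs <- orfs[grepl("^lnc", orfs$transcript), , drop = FALSE]
  lnc_orfs <- cistronic_rank(lnc_orfs)
  can_orfs <- sim$canonical

  framing_all <- list()
  expr_all <- list()
  for (stage in config$stages) {
    for (replica in config$replicas) {
      ribo <- simulate_reads(sim, "ribo", stage, replica)
      rna <- simulate_reads(sim, "rna", stage, replica)
      calib <- calibrate_frames(assign_frames(ribo, can_orfs))
      prof <- assign_frames(ribo, lnc_orfs)
      calls <- call_framing(prof, calib, alpha = alpha,
                            stage = stage, replica = replica)
      framing_all[[paste(stage, replica)]] <- calls
      fp_cnt <- orf_read_counts(ribo, lnc_orfs, lengths = config$rpf_lengths)
      rna_cnt <- orf_read_counts(rna, lnc_orfs)
      len_nt <- lnc_orfs$end - lnc_orfs$start
      framed_any <- tapply(calls$framed, calls$orf_id, any)
      expr_all[[paste(stage, replica)]] <- data.frame(
        orf_id = lnc_orfs$orf_id, stage = stage, replica = replica,
        rpkm_fp = rpkm(fp_cnt, len_nt, ribo$library_size),
        rpkm_rna = rpkm(rna_cnt, len_nt, rna$library_size),
        framed = as.logical(framed_any[lnc_orfs$orf_id]) %in% TRUE,
        stringsAsFactors = FALSE)
    }
  }
  framing <- do.call(rbind, framing_all)
  expression <- do.call(rbind, expr_all)
  rownames(framing) <- rownames(expression) <- NULL

  status_rows <- list()
  for (stage in config$stages) {
    eT <- expression[expression$stage == stage &
                     expression$replica == config$replicas[1], ]
    eB <- expression[expression$stage == stage &
                     expression$replica == config$replicas[2], ]
    eB <- eB[match(eT$orf_id, eB$orf_id), ]
    status_rows[[stage]] <- data.frame(
      orf_id = eT$orf_id, stage = stage,
      status = classify_status(eT$rpkm_rna, eB$rpkm_rna,
                               eT$rpkm_fp, eB$rpkm_fp,
                               eT$framed, eB$framed,
                               rpkm_threshold = rpkm_threshold),
      stringsAsFactors = FALSE)
  }
  status <- do.call(rbind, status_rows)
  rownames(status) <- NULL
  stage_sum <- stage_summary(status)

  # TE per ORF per stage (replica-averaged RPKMs), Z-ratios on ORFs
  # transcribed at every stage with positive footprint signal throughout.
  te_tab <- stats::aggregate(cbind(rpkm_fp, rpkm_rna) ~ orf_id + stage,
                             data = expression, FUN = mean)
  te_wide <- stats::reshape(te_tab, idvar = "orf_id", timevar = "stage",
                            direction = "wide")
  const_tx <- stage_sum$orf_id[stage_sum$transcription == "constitutive"]
  te_changes <- list()
  for (i in seq_len(length(config$stages) - 1)) {
    a <- config$stages[i]; b <- config$stages[i + 1]
    fa <- te_wide[[paste0("rpkm_fp.", a)]]; ra <- te_wide[[paste0("rpkm_rna.", a)]]
    fb <- te_wide[[paste0("rpkm_fp.", b)]]; rb <- te_wide[[paste0("rpkm_rna.", b)]]
    ok <- te_wide$orf_id %in% const_tx & fa > 0 & fb > 0 & ra > 0 & rb > 0
    if (sum(ok) >= 3) {
      tab <- data.frame(orf_id = te_wide$orf_id[ok],
                        te_a = translational_efficiency(fa[ok], ra[ok]),
                        te_b = translational_efficiency(fb[ok], rb[ok]))
      te_changes[[paste(a, b, sep = "->")]] <-
        te_z_ratios(tab, threshold = te_threshold,
                    transition = paste(a, b, sep = "->"))
    }
  }
  te_changes <- if (length(te_changes)) do.call(rbind, te_changes) else NULL
  if (!is.null(te_changes)) rownames(te_changes) <- NULL

  kozak_model <- build_kozak_model(
    extract_kozak_context(sim$transcripts, can_orfs))
  kozak <- data.frame(
    orf_id = lnc_orfs$orf_id,
    context = extract_kozak_context(sim$transcripts, lnc_orfs),
    stringsAsFactors = FALSE)
  kozak$score <- kozak_score(kozak$context, kozak_model)

  ref_usage <- codon_usage(can_orfs$nt_seq)
  milc_scores <- vapply(lnc_orfs$nt_seq, function(s)
    milc(s, ref_usage)$milc, numeric(1), USE.NAMES = FALSE)
  milc_tab <- data.frame(orf_id = lnc_orfs$orf_id, milc = milc_scores,
                         stringsAsFactors = FALSE)

  # ribo-bound ORFs (any status from ribo_bound_only upward, any stage)
  bound_ids <- unique(status$orf_id[status$status %in%
                                    c("ribo_bound_only", "limited", "robust")])
  per_tx <- table(factor(
    lnc_orfs$transcript[lnc_orfs$orf_id %in% bound_ids],
    levels = unique(lnc_orfs$transcript)))
  clustering <- poisson_clustering(as.integer(per_tx))

  result <- list(orfs = lnc_orfs, framing = framing, expression = expression,
                 status = status, stage_summary = stage_sum,
                 te_changes = te_changes, kozak = kozak, milc = milc_tab,
                 clustering = clustering, truth = sim$truth)

  if (run_homology) {
    robust_ids <- unique(status$orf_id[status$status == "robust"])
    queries <- lnc_orfs[lnc_orfs$orf_id %in% robust_ids, , drop = FALSE]
    if (nrow(queries) > 0) {
      ev <- evolve_homologues(queries, omega = homology_omega,
                              t = homology_t, species = "sim_species",
                              seed = config$seed + 7L)
      query_db <- smorf_db(stats::setNames(lnc_orfs$peptide, lnc_orfs$orf_id),
                           species = "query_species")
      hits <- lapply(queries$orf_id, function(q)
        search_and_validate(q, query_db, ev$db))
      hom <- do.call(rbind, lapply(seq_along(hits), function(i) {
        h <- hits[[i]]
        if (is.null(h)) return(NULL)
        data.frame(query = h$query, species = h$species, target = h$target,
                   identity = h$identity, genor_score = h$genor_score,
                   reciprocal_ok = h$reciprocal_ok, stringsAsFactors = FALSE)
      }))
      dnds_tab <- do.call(rbind, lapply(seq_len(nrow(queries)), function(i) {
        anc <- queries$nt_seq[i]
        anc_cds <- substr(anc, 1, 3 * queries$n_codons[i])
        ev_nt <- ev$nt[paste0("sim_species_hom_", queries$orf_id[i])]
        ev_cds <- substr(ev_nt, 1, 3 * queries$n_codons[i])
        r <- li93_dnds(anc_cds, ev_cds)
        data.frame(orf_id = queries$orf_id[i], dN = r$dN, dS = r$dS,
                   dnds = r$dnds, stringsAsFactors = FALSE)
      }))
      result$homology <- hom
      result$dnds <- dnds_tab
    }
  }

  result$manifest <- list(
    seed = config$seed, alpha = alpha, rpkm_threshold = rpkm_threshold,
    te_threshold = te_threshold, null_frame_probability = 1/3,
    rpf_lengths = as.integer(config$rpf_lengths),
    framing_fidelity = config$framing_fidelity,
    library_size = config$library_size,
    genor_weights = list(identical = 100, strong = 70, weak = 30),
    genor_score_floor = 0.4, min_identity_percent = 50,
    stages = config$stages, replicas = config$replicas)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, name) {
      if (!is.null(df))
        utils::write.table(df, file.path(outdir, paste0(name, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_fasta(sim$transcripts, file.path(outdir, "transcripts.fasta"))
    w(result$orfs[setdiff(names(result$orfs), "nt_seq")], "orfs")
    w(result$framing, "framing")
    w(result$expression, "expression")
    w(result$status, "status")
    w(result$stage_summary, "stage_summary")
    w(result$te_changes, "te_zratios")
    w(result$kozak, "kozak")
    w(result$milc, "milc")
    w(result$truth, "truth")
    if (!is.null(result$homology)) w(result$homology, "homology")
    if (!is.null(result$dnds)) w(result$dnds, "dnds")
    yaml::write_yaml(result$manifest, file.path(outdir, "manifest.yaml"))
  }
  structure(result, class = "pipeline_result")
}
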