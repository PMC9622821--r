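#' Split ribosome footprints by reading frame, per ORF and RPF length
#'
#' Counts the 5' ends of ribosome-protected fragments (RPFs) falling inside
#' each ORF body, split by read length and reading frame
#' `(pos5 - orf_start) mod 3`. Reads whose 5' end lies in the -18/+15 nt
#' flanks around the ORF are kept in a separate flank table (metagene use)
#' and never enter the framing-test counts. Reads attribute by raw 5' end
#' with no P-site offsetting: the per-length calibration absorbs constant
#' offsets.
#'
#' @param reads A [read_table()].
#' @param orfs ORF data.frame ([find_orfs()] output).
#' @param lengths RPF lengths to keep; rows outside are ignored with a tally
#'   in a message.
#' @param flank_up,flank_down Flank widths (nt) upstream/downstream kept for
#'   metagene output.
#' @return data.frame (class `frame_profile`) with columns `orf_id`,
#'   `length`, `frame`, `count` on the complete grid of lengths x frames;
#'   attribute `flank` holds the flank reads.
#' @export
assign_frames <- function(reads, orfs, lengths = 26:36,
                          flank_up = 18, flank_down = 15) {
  stopifnot(inherits(reads, "read_table"))
  rd <- reads$reads
  n_ignored <- sum(rd$count[!(rd$length %in% lengths)])
  if (n_ignored > 0)
    message("assign_frames: ignored ", n_ignored,
            " read(s) with RPF length outside [",
            min(lengths), ", ", max(lengths), "]")
  rd <- rd[rd$length %in% lengths & rd$count > 0, , drop = FALSE]
  grid <- expand.grid(orf_id = orfs$orf_id, length = lengths, frame = 0:2,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$orf_id, grid$length, grid$frame), ]
  rownames(grid) <- NULL
  flank <- data.frame(orf_id = character(0), pos_rel = integer(0),
                      length = integer(0), count = numeric(0))
  if (nrow(rd) > 0 && nrow(orfs) > 0) {
    m <- merge(rd, orfs[c("orf_id", "transcript", "start", "end")],
               by = "transcript")
    body <- m[m$pos5 >= m$start & m$pos5 < m$end, , drop = FALSE]
    if (nrow(body) > 0) {
      body$frame <- (body$pos5 - body$start) %% 3L
      agg <- stats::aggregate(count ~ orf_id + length + frame, data = body, FUN = sum)
      key <- function(d) paste(d$orf_id, d$length, d$frame)
      idx <- match(key(grid), key(agg))
      grid$count <- ifelse(is.na(idx), 0, agg$count[idx])
    } else grid$count <- 0
    fl <- m[(m$pos5 >= m$start - flank_up & m$pos5 < m$start) |
            (m$pos5 >= m$end & m$pos5 < m$end + flank_down), , drop = FALSE]
    if (nrow(fl) > 0)
      flank <- data.frame(orf_id = fl$orf_id, pos_rel = fl$pos5 - fl$start,
                          length = fl$length, count = fl$count)
  } else grid$count <- 0
  structure(grid, flank = flank, class = c("frame_profile", "data.frame"))
}

#' Calibrate the expected reading frame per RPF length
#'
#' Sums frame-split counts over a set of canonical (annotated, known
#' translated) ORFs and defines, per RPF length, the dominant frame as the
#' properly translated frame. Exact ties resolve to the lowest frame index
#' and flag the length as ambiguous; lengths with zero reads get no expected
#' frame. Calibration is always performed on the same sample
#' (replica x stage) whose candidate ORFs will be tested, because framing
#' patterns vary between samples.
#'
#' @param profiles A `frame_profile` (from [assign_frames()] on canonical
#'   ORFs), or any data.frame with `length`, `frame`, `count`.
#' @return List of class `frame_calibration`: `expected_frame` (named
#'   integer, NA where no reads), `support` (fraction of reads in the
#'   dominant frame), `ambiguous` (logical), `n_reads`.
#' @export
calibrate_frames <- function(profiles) {
  tot <- stats::aggregate(count ~ length + frame, data = profiles, FUN = sum)
  lengths <- sort(unique(profiles$length))
  expected <- support <- stats::setNames(rep(NA_real_, length(lengths)),
                                         lengths)
  ambiguous <- stats::setNames(rep(FALSE, length(lengths)), lengths)
  n_reads <- stats::setNames(numeric(length(lengths)), lengths)
  for (L in lengths) {
    cnt <- stats::setNames(rep(0, 3), 0:2)
    sub <- tot[tot$length == L, ]
    cnt[as.character(sub$frame)] <- sub$count
    n <- sum(cnt)
    n_reads[as.character(L)] <- n
    if (n == 0) next
    expected[as.character(L)] <- as.integer(which.max(cnt)) - 1L
    support[as.character(L)] <- max(cnt) / n
    ambiguous[as.character(L)] <- sum(cnt == max(cnt)) > 1
  }
  structure(list(expected_frame = expected, support = support,
                 ambiguous = ambiguous, n_reads = n_reads),
            class = "frame_calibration")
}

#' Exact binomial framing test
#'
#' One-sided upper-tail exact binomial test for an excess of reads in the
#' expected frame: `p = P(X >= k | n, p0)` with null success probability
#' `p0 = 1/3` (three frames, no prior). An ORF/length is called framed when
#' `p < alpha` and `n > 0`. Vectorised over `n` and `k`.
#'
#' @param n Total reads at this RPF length inside the ORF body.
#' @param k Reads in the expected frame.
#' @param alpha Significance level (default 0.01).
#' @param p0 Null per-read probability of the expected frame.
#' @return data.frame with `n`, `k`, `p_value`, `framed`.
#' @export
framing_test <- function(n, k, alpha = 0.01, p0 = 1/3) {
  stopifnot(length(n) == length(k), all(k >= 0), all(k <= n))
  p <- ifelse(n == 0, NA_real_,
              stats::pbinom(k - 1, n, p0, lower.tail = FALSE))
  data.frame(n = n, k = k, p_value = p,
             framed = !is.na(p) & p < alpha & n > 0)
}

#' Per-ORF framing calls across RPF lengths
#'
#' Applies the calibrated expected frame and the binomial framing test to
#' every (ORF, RPF length) pair of a sample. Lengths whose calibration has
#' no expected frame are skipped.
#'
#' @param profiles `frame_profile` for the candidate ORFs of one sample.
#' @param calibration `frame_calibration` from the same sample's canonical
#'   ORFs.
#' @param alpha Significance level.
#' @param stage,replica Optional sample labels copied into the output.
#' @return data.frame with `orf_id`, `length`, `stage`, `replica`, `n`, `k`,
#'   `p_value`, `framed`.
#' @export
call_framing <- function(profiles, calibration, alpha = 0.01,
                         stage = NA_character_, replica = NA_character_) {
  stopifnot(inherits(calibration, "frame_calibration"))
  ef <- calibration$expected_frame
  lengths <- as.integer(names(ef))[!is.na(ef)]
  prof <- profiles[profiles$length %in% lengths, , drop = FALSE]
  if (nrow(prof) == 0)
    return(data.frame(orf_id = character(0), length = integer(0),
                      stage = character(0), replica = character(0),
                      n = numeric(0), k = numeric(0), p_value = numeric(0),
                      framed = logical(0)))
  ntab <- stats::aggregate(count ~ orf_id + length, data = prof, FUN = sum)
  names(ntab)[names(ntab) == "count"] <- "n"
  exp_frame <- ef[as.character(prof$length)]
  kprof <- prof[prof$frame == exp_frame, , drop = FALSE]
  ktab <- stats::aggregate(count ~ orf_id + length, data = kprof, FUN = sum)
  names(ktab)[names(ktab) == "count"] <- "k"
  tab <- merge(ntab, ktab, by = c("orf_id", "length"), all.x = TRUE)
  tab$k[is.na(tab$k)] <- 0
  res <- framing_test(tab$n, tab$k, alpha = alpha)
  out <- data.frame(orf_id = tab$orf_id, length = tab$length,
                    stage = stage, replica = replica,
                    n = tab$n, k = tab$k, p_value = res$p_value,
                    framed = res$framed, stringsAsFactors = FALSE)
  out[order(out$orf_id, out$length), ]
}

#' Count independent translation events per ORF
#'
#' A translation event is a distinct (RPF length, replica, stage) triple
#' with a positive framing call; framing detected in different footprint
#' lengths, replicas or stages reflects independent ribonuclease-protection
#' events and therefore independent support for translation.
#'
#' @param calls Framing-call data.frame (rows from [call_framing()], possibly
#'   pooled over samples) with columns `orf_id`, `length`, `replica`,
#'   `stage`, `framed`.
#' @return Named integer vector: events per `orf_id` (ORFs present in
#'   `calls` only).
#' @export
count_translation_events <- function(calls) {
  if (nrow(calls) == 0) return(stats::setNames(integer(0), character(0)))
  framed <- calls[calls$framed, , drop = FALSE]
  framed <- framed[!duplicated(framed[c("orf_id", "length", "replica", "stage")]), ]
  tab <- table(factor(framed$orf_id, levels = unique(calls$orf_id)))
  stats::setNames(as.integer(tab), names(tab))
}

#' Spearman correlation of global framing patterns between two ORF classes
#'
#' Each class's frame profile is summed to a 33-vector (11 RPF lengths x 3
#' frames) of class-total counts; the statistic is the Spearman rank
#' correlation between the two vectors.
#'
#' @param profiles_a,profiles_b `frame_profile` data.frames covering the same
#'   lengths.
#' @return Spearman rho (NA with a warning if either vector has zero
#'   variance).
#' @export
framing_pattern_correlation <- function(profiles_a, profiles_b) {
  v <- function(p) {
    tot <- stats::aggregate(count ~ length + frame, data = p, FUN = sum)
    grid <- expand.grid(length = sort(unique(p$length)), frame = 0:2)
    idx <- match(paste(grid$length, grid$frame), paste(tot$length, tot$frame))
    ifelse(is.na(idx), 0, tot$count[idx])
  }
  a <- v(profiles_a); b <- v(profiles_b)
  stopifnot(length(a) == length(b))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("framing_pattern_correlation: zero-variance class vector")
    return(NA_real_)
  }
  stats::cor(a, b, method = "spearman")
}
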