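# Independent oracles used by the tests. Each is written from first
# principles, deliberately avoiding the package's own code paths.

# upper-tail binomial probability by direct pmf summation
oracle_binom_upper <- function(n, k, p = 1/3) {
  if (n == 0) return(NA_real_)
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i),
             numeric(1)))
}

# exhaustive AUG->STOP enumeration on a short sequence: character walk,
# first in-frame stop, length bounds, then 5'-most start per (stop, frame)
oracle_find_orfs <- function(seq, min_codons = 10, max_codons = 150) {
  ch <- strsplit(seq, NULL)[[1]]
  n <- length(ch)
  stops <- c("TAA", "TAG", "TGA")
  cand <- list()
  for (s in seq_len(n - 2)) {
    if (paste(ch[s:(s + 2)], collapse = "") != "ATG") next
    j <- s + 3
    while (j + 2 <= n) {
      cod <- paste(ch[j:(j + 2)], collapse = "")
      if (cod %in% stops) {
        nc <- (j - s) / 3
        orf_nt <- paste(ch[s:(j + 2)], collapse = "")
        if (nc >= min_codons && nc <= max_codons &&
            !grepl("N", orf_nt, fixed = TRUE))
          cand[[length(cand) + 1]] <- c(start = s - 1, end = j + 2,
                                        stop = j, frame = (s - 1) %% 3)
        break
      }
      j <- j + 3
    }
  }
  if (length(cand) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  df <- as.data.frame(do.call(rbind, cand))
  keep <- unlist(lapply(split(seq_len(nrow(df)), paste(df$stop, df$frame)),
                        function(i) i[which.min(df$start[i])]))
  df <- df[sort(keep), c("start", "end")]
  df[order(df$start), , drop = FALSE]
}

# hypergeometric upper tail by direct enumeration (feasible for N <= 30)
oracle_hyper_upper <- function(obs, n1, n2, N) {
  ks <- obs:min(n1, n2)
  sum(vapply(ks, function(k)
    choose(n1, k) * choose(N - n1, n2 - k) / choose(N, n2), numeric(1)))
}

# Nei-Gojobori (1986) pairwise dN/dS with Jukes-Cantor correction;
# independent of the package's Li-method implementation.
oracle_ng86 <- function(a, b) {
  gcode <- Biostrings::GENETIC_CODE
  names(gcode) <- chartr("U", "T", names(gcode))
  bases <- c("A", "C", "G", "T")
  syn_sites <- function(cod) {
    ch <- strsplit(cod, NULL)[[1]]
    s <- 0
    for (p in 1:3) for (nb in setdiff(bases, ch[p])) {
      mut <- ch; mut[p] <- nb
      mcod <- paste(mut, collapse = "")
      if (gcode[mcod] != "*" && gcode[mcod] == gcode[cod]) s <- s + 1/3
    }
    s
  }
  path_counts <- function(c1, c2) {
    # average syn/nonsyn difference counts over all mutational paths that
    # avoid stop codons
    dpos <- which(strsplit(c1, NULL)[[1]] != strsplit(c2, NULL)[[1]])
    if (length(dpos) == 0) return(c(0, 0))
    perms <- if (length(dpos) == 1) list(dpos) else {
      if (length(dpos) == 2) list(dpos, rev(dpos)) else {
        idx <- list()
        for (i in 1:3) for (j in setdiff(1:3, i))
          idx[[length(idx) + 1]] <- dpos[c(i, j, setdiff(1:3, c(i, j)))]
        idx
      }
    }
    tot <- c(0, 0); used <- 0
    for (ord in perms) {
      cur <- strsplit(c1, NULL)[[1]]
      tgt <- strsplit(c2, NULL)[[1]]
      sd <- nd <- 0; ok <- TRUE
      for (p in ord) {
        prev <- paste(cur, collapse = "")
        cur[p] <- tgt[p]
        nxt <- paste(cur, collapse = "")
        if (gcode[nxt] == "*") { ok <- FALSE; break }
        if (gcode[nxt] == gcode[prev]) sd <- sd + 1 else nd <- nd + 1
      }
      if (ok) { tot <- tot + c(sd, nd); used <- used + 1 }
    }
    if (used == 0) return(c(0, length(dpos)))   # all paths hit stops
    tot / used
  }
  n <- nchar(a)
  st <- seq(1, n, 3)
  ca <- substring(a, st, st + 2); cb <- substring(b, st, st + 2)
  keep <- gcode[ca] != "*" & gcode[cb] != "*" &
    !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  ca <- ca[keep]; cb <- cb[keep]
  S <- mean(c(sum(vapply(ca, syn_sites, 0)), sum(vapply(cb, syn_sites, 0))))
  N <- 3 * length(ca) - S
  d <- rowSums(vapply(seq_along(ca), function(i) path_counts(ca[i], cb[i]),
                      numeric(2)))
  pS <- d[1] / S; pN <- d[2] / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  dS <- jc(pS); dN <- jc(pN)
  list(dS = dS, dN = dN, dnds = if (!is.na(dS) && dS > 0) dN / dS else NA_real_)
}

revcomp_str <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), NULL)[[1]]), collapse = "")
}

# shared tiny fixture: deterministic random transcript over ACGT
random_transcript <- function(len, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
}

random_contexts <- function(n, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = ""),
    character(1))
}
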