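test_that("Kozak model weights are log odds with pseudocounts", {
  # all contexts identical: per-position f equals background g -> weights 0
  m <- build_kozak_model(rep("AAAAAAAA", 10))
  expect_equal(unname(m$weights["A", ]), rep(0, 8))
  expect_equal(kozak_score("AAAAAAAA", m, centered = FALSE), 0)
  # nucleotides absent from the whole pool are pure pseudocount on both
  # sides of the odds ratio: finite weight, never -Inf
  expect_true(all(is.finite(m$weights)))
  expect_true(all(m$weights[c("C", "G", "T"), ] <= 0))
  expect_lte(kozak_score("AAAAAAAC", m, centered = FALSE), 0)
  # a nucleotide absent at one position but present in the pool weighs
  # finitely negative there
  m_mix <- build_kozak_model(c(rep("AAAAAAAA", 5), rep("CAAAAAAA", 5)))
  expect_lt(m_mix$weights["C", 2], 0)
  expect_true(is.finite(m_mix$weights["C", 2]))

  # frequency arithmetic oracle: A at one position in half of 10 contexts
  ctx <- c(rep("AAAAAAAA", 5), rep("CAAAAAAA", 5))
  m2 <- build_kozak_model(ctx)
  n <- 10
  f_A1 <- (5 + 1) / (n + 4)
  g_A <- (75 + 8) / (8 * (n + 4))     # 75 A's pooled over all 8 positions
  expect_equal(unname(m2$weights["A", 1]), log(f_A1 / g_A))
  f_C1 <- (5 + 1) / (n + 4)
  g_C <- (5 + 8) / (8 * (n + 4))
  expect_equal(unname(m2$weights["C", 1]), log(f_C1 / g_C))
})

test_that("Kozak scoring is centered and maximal at the argmax context", {
  ctx <- random_contexts(60, 313)
  m <- build_kozak_model(ctx)
  # centering identity: mean centered score over training contexts is 0
  expect_equal(mean(kozak_score(ctx, m)), 0, tolerance = 1e-12)
  # exhaustive maximality over all 4^8 contexts
  best <- paste(rownames(m$weights)[apply(m$weights, 2, which.max)],
                collapse = "")
  grid <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), 8))
  all_ctx <- do.call(paste0, grid)
  scores <- kozak_score(all_ctx, m, centered = FALSE)
  expect_equal(max(scores), kozak_score(best, m, centered = FALSE))
  expect_error(kozak_score("AAAAAAAU", m), "restricted")
  expect_error(kozak_score("AAAA", m), "8-mers")
  expect_error(build_kozak_model("AAAA"), "8-mers")
})

test_that("context extraction reads -5..-1 and +4..+6 around the start", {
  #                 0123456789
  seq <- paste0("GGTAC", "ATG", "CCA", "TTTTTTTTTTTTTTTTTTTTTTTTTTTTTTAA")
  orfs <- data.frame(orf_id = c("o1", "o2"), transcript = "t1",
                     start = c(5, 2), end = c(41, 41))
  ctx <- extract_kozak_context(transcript_set(c(t1 = seq)), orfs)
  expect_equal(unname(ctx["o1"]), "GGTACCCA")
  expect_true(is.na(ctx["o2"]))      # window off the 5' end
})

test_that("planted Kozak strength is recovered by the scorer", {
  cfg <- sim_config(seed = 5, n_lncrnas = 120, n_canonical = 40,
                    orfs_per_transcript = c(3, 6))
  sim <- suppressMessages(simulate_transcriptome(cfg))
  m <- build_kozak_model(extract_kozak_context(sim$transcripts, sim$canonical))
  sc <- kozak_score(extract_kozak_context(sim$transcripts, sim$orfs), m)
  expect_gte(sum(!is.na(sc)), 500)
  rho <- cor(sim$truth$kozak_strength, sc, method = "spearman",
             use = "complete.obs")
  expect_gt(rho, 0.9)
})

test_that("cistronic rank is status-blind and 5'->3'", {
  orfs <- data.frame(orf_id = paste0("o", 1:5),
                     transcript = c("t1", "t1", "t1", "t2", "t2"),
                     start = c(100, 5, 40, 9, 2))
  r <- cistronic_rank(orfs)
  expect_equal(r$cistronic_rank, c(3, 1, 2, 2, 1))
})

test_that("MILC matches direct-sum arithmetic and its boundary cases", {
  ref <- codon_usage(paste(rep(lncorf:::.sense_codons(), 10), collapse = ""))

  # Met/Trp only: all families single-codon, sum M = 0, C = 0
  r <- milc(c("ATG", "TGG", "ATG"), ref)
  expect_equal(r$milc, 0)
  expect_equal(unname(r$M[c("M", "W")]), c(0, 0))

  # one codon per amino acid vs uniform-within-family reference:
  # direct-sum oracle M_a = 2 * o * ln(r_a)
  fams <- lncorf:::.codon_families()
  one_per_aa <- vapply(fams, `[`, character(1), 1)
  r1 <- milc(rep(one_per_aa, 5), ref)
  L <- 5 * length(one_per_aa)
  M_expect <- sum(vapply(fams, function(f) 2 * 5 * log(length(f)),
                         numeric(1)))
  C_expect <- sum(vapply(fams, function(f) length(f) - 1, numeric(1))) / L
  expect_equal(r1$milc, M_expect / L - C_expect)
  expect_gt(r1$milc, 1)

  # sampling from the reference scores near zero
  set.seed(99)
  near0 <- replicate(40, {
    cods <- sample(names(ref), 1000, TRUE, prob = ref / sum(ref))
    milc(cods, ref)$milc
  })
  expect_gte(mean(abs(near0) < 0.1), 0.95)

  # duplication invariance up to the 1/L correction drift
  set.seed(100)
  s <- paste(sample(lncorf:::.sense_codons(), 600, TRUE), collapse = "")
  expect_lt(abs(milc(s, ref)$milc - milc(paste0(s, s), ref)$milc), 0.05)

  # missing reference codon falls back to pseudocounts with a message
  ref2 <- ref; ref2["TTT"] <- 0
  expect_message(m2 <- milc(c("TTT", "TTC", "ATG", rep("GGA", 10)), ref2),
                 "pseudocount")
  expect_true(is.finite(m2$milc))
})

test_that("amino-acid usage pools to frequencies summing to one", {
  expect_equal(unname(aa_usage_profile("MM")["M"]), 1)
  p <- aa_usage_profile(c("MW", "WM"))
  expect_equal(unname(p[c("M", "W")]), c(0.5, 0.5))
  set.seed(12)
  peps <- vapply(1:5, function(i)
    paste(sample(names(aa_usage_profile("ACDEFGHIKLMNPQRSTVWY")), 30, TRUE),
          collapse = ""), character(1))
  expect_equal(sum(aa_usage_profile(peps)), 1)
  expect_error(aa_usage_profile(character(0)), "empty")
})
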