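test_that("smORF databases enforce the 10-150 AA window in translation", {
  pep <- function(nc) paste0("ATG", strrep("GAA", nc - 1), "TAA")
  ts <- transcript_set(c(p9 = pep(9), p10 = pep(10), p150 = pep(150),
                         p151 = pep(151)))
  db <- build_smorf_db(ts, species = "sp", six_frame = FALSE)
  expect_setequal(nchar(db$peptide), c(10, 150))
  # reverse-complement ORF appears only in six-frame mode
  ts_rc <- transcript_set(c(rc = revcomp_str(pep(20))))
  expect_equal(nrow(build_smorf_db(ts_rc, six_frame = FALSE)), 0)
  expect_equal(nrow(build_smorf_db(ts_rc, six_frame = TRUE)), 1)
  # dedup by peptide sequence
  ts_dup <- transcript_set(c(a = pep(20), b = pep(20)))
  expect_equal(nrow(build_smorf_db(ts_dup, six_frame = FALSE)), 1)
})

test_that("reciprocal best-hit validation accepts self, rejects paralogs", {
  set.seed(61)
  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
          "T","V","W","Y")
  rand_pep <- function(n) paste(sample(aa, n, TRUE), collapse = "")
  q <- rand_pep(30)
  qdb <- smorf_db(c(q1 = q), species = "dmel")

  # exact copy in the target database: validated, perfect score
  tdb <- smorf_db(c(h1 = q), species = "dsim")
  hit <- search_and_validate("q1", qdb, tdb)
  expect_equal(hit$target, "h1")
  expect_true(hit$reciprocal_ok)
  expect_equal(hit$genor_score, 100)
  expect_equal(hit$identity, 100)

  # unrelated random peptides: nothing above the score floor
  tdb_rand <- smorf_db(setNames(vapply(1:20, function(i) rand_pep(30), ""),
                                paste0("r", 1:20)), species = "dsim")
  expect_null(search_and_validate("q1", qdb, tdb_rand))
  expect_null(search_and_validate("q1", qdb,
                                  smorf_db(character(0), species = "empty")))

  # paralog trap: the target's best reciprocal hit is q2, not q1
  q1 <- rand_pep(40)
  q2 <- chartr("LKE", "VRD", q1)      # conservative paralog of q1
  qtrap <- smorf_db(c(q1 = q1, q2 = q2), species = "dmel")
  ttrap <- smorf_db(c(t1 = q2), species = "dsim")
  h <- search_and_validate("q1", qtrap, ttrap)
  expect_null(h)                       # t1 reciprocates to q2
  expect_equal(search_and_validate("q2", qtrap, ttrap)$target, "t1")
})

test_that("conservation annotation follows the */:/./gap tiers", {
  expect_equal(annotate_conservation("MKV", "MKV"), "***")
  expect_equal(substr(annotate_conservation("K", "R"), 1, 1), ":")  # PAM250 3
  expect_equal(annotate_conservation("A", "-"), " ")
  expect_equal(annotate_conservation("-", "A"), " ")
  # weak tier: C/A share the CSA group while PAM250(C,A) = -2
  expect_equal(annotate_conservation("C", "A"), ".")
  # dissimilar pair outside every group
  expect_equal(annotate_conservation("W", "G"), " ")
  expect_error(annotate_conservation("MK", "M"), "equal length")
})

test_that("the conservation-weighted score is exact arithmetic", {
  expect_equal(genor_score(strrep("*", 30), 30), 100)
  expect_equal(genor_score("*****::. ", 10), 67)
  expect_equal(genor_score("          ", 25), 0)
  expect_error(genor_score("***", 0), "query_length")
  # monotone under downgrades * -> : -> . -> ' '
  ann <- strrep("*", 10)
  downgrade <- c("*" = ":", ":" = ".", "." = " ")
  prev <- genor_score(ann, 10)
  for (d in names(downgrade)) {
    ann <- sub(d, downgrade[[d]], ann, fixed = TRUE)
    cur <- genor_score(ann, 10)
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("planted homologues are recovered without decoy acceptances", {
  cfg <- sim_config(seed = 9, n_lncrnas = 20, n_canonical = 5)
  sim <- suppressMessages(simulate_transcriptome(cfg))
  orfs <- head(sim$orfs, 12)
  ev <- evolve_homologues(orfs, omega = 0.5, t = 0.3, species = "spA",
                          decoys_per_orf = 10, seed = 4)
  qdb <- smorf_db(setNames(orfs$peptide, orfs$orf_id), species = "dmel")
  hits <- lapply(orfs$orf_id, function(q) search_and_validate(q, qdb, ev$db))
  found <- vapply(hits, function(h) if (is.null(h)) NA_character_ else
    h$target, character(1))
  expect_false(any(grepl("decoy", found), na.rm = TRUE))
  expect_gte(mean(found == ev$truth$target, na.rm = TRUE), 0.9)
})

test_that("RBH validation is symmetric on unique-best instances", {
  set.seed(63)
  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
          "T","V","W","Y")
  peps_a <- setNames(vapply(1:6, function(i)
    paste(sample(aa, 35, TRUE), collapse = ""), ""), paste0("a", 1:6))
  # b peptides: lightly mutated copies, unique best partners
  mutate <- function(p) {
    ch <- strsplit(p, NULL)[[1]]
    i <- sample(seq_along(ch), 4)
    ch[i] <- sample(aa, 4, TRUE)
    paste(ch, collapse = "")
  }
  peps_b <- setNames(vapply(peps_a, mutate, ""), paste0("b", 1:6))
  dba <- smorf_db(peps_a, species = "A")
  dbb <- smorf_db(peps_b, species = "B")
  for (i in 1:6) {
    hf <- search_and_validate(paste0("a", i), dba, dbb)
    expect_equal(hf$target, paste0("b", i))
    hr <- search_and_validate(paste0("b", i), dbb, dba)
    expect_equal(hr$target, paste0("a", i))
  }
})

test_that("conservation depth counts validated species and finds the deepest", {
  mk <- function(ident, score = 80) structure(
    list(reciprocal_ok = TRUE, identity = ident, genor_score = score),
    class = "homology_hit")
  hits <- list(dsim = mk(90), dsec = NULL, dvir = mk(60))
  d <- conservation_depth(hits)
  expect_equal(d$n_species, 2)
  expect_equal(d$deepest_species, "dvir")
  expect_equal(conservation_depth(list(dsim = mk(90), dvir = NULL))$deepest_species,
               "dsim")
  none <- conservation_depth(list(dsim = mk(40), dvir = NULL))
  expect_equal(none$n_species, 0)
  expect_true(is.na(none$deepest_species))
})
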