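make_reads <- function(rows, lib = 1e6) {
  read_table(do.call(rbind, lapply(rows, function(r)
    data.frame(transcript = r[[1]], pos5 = as.integer(r[[2]]),
               length = as.integer(r[[3]]), count = as.numeric(r[[4]])))),
    library_size = lib)
}

orf1 <- data.frame(orf_id = "o1", transcript = "t1", start = 60, end = 120,
                   strand = "+", stringsAsFactors = FALSE)

test_that("frame assignment uses mod-3 arithmetic inside the ORF body", {
  rt <- make_reads(list(list("t1", 60, 32, 7),    # frame 0 at start
                        list("t1", 64, 30, 2),    # frame 1
                        list("t1", 54, 32, 5),    # -6: flank, excluded
                        list("t1", 119, 28, 1),   # last body position
                        list("t1", 120, 28, 9)))  # past end: flank
  prof <- assign_frames(rt, orf1)
  get <- function(L, f) prof$count[prof$length == L & prof$frame == f]
  expect_equal(get(32, 0), 7)
  expect_equal(get(30, 1), 2)
  expect_equal(get(28, 2), 1)      # (119-60) %% 3 == 2
  expect_equal(sum(prof$count), 10)
  fl <- attr(prof, "flank")
  expect_setequal(fl$pos_rel, c(-6, 60))
})

test_that("reads with lengths outside the RPF range are tallied and ignored", {
  rt <- make_reads(list(list("t1", 60, 32, 3), list("t1", 60, 50, 4)))
  expect_message(prof <- assign_frames(rt, orf1), "4 read")
  expect_equal(sum(prof$count), 3)
})

test_that("calibration picks the dominant frame and flags ties and gaps", {
  prof <- data.frame(orf_id = "c1",
                     length = rep(c(30, 32, 29, 31), each = 3),
                     frame = rep(0:2, 4),
                     count = c(90, 5, 5,     # 30 -> frame 0
                               5, 5, 90,     # 32 -> frame 2
                               5, 5, 5,      # 29 -> tie
                               0, 0, 0))     # 31 -> no reads
  cal <- calibrate_frames(prof)
  expect_equal(cal$expected_frame[["30"]], 0)
  expect_equal(cal$expected_frame[["32"]], 2)
  expect_equal(cal$expected_frame[["29"]], 0)      # tie -> lowest frame
  expect_true(cal$ambiguous[["29"]])
  expect_true(is.na(cal$expected_frame[["31"]]))
  expect_equal(cal$support[["30"]], 0.9)
})

test_that("binomial framing test matches closed forms and the pmf oracle", {
  expect_equal(framing_test(5, 5)$p_value, (1/3)^5)
  expect_true(framing_test(5, 5)$framed)
  expect_equal(framing_test(4, 4)$p_value, (1/3)^4)
  expect_false(framing_test(4, 4)$framed)           # smallest passing n is 5
  expect_equal(framing_test(15, 5)$p_value, 0.596, tolerance = 1e-3)
  expect_false(framing_test(15, 5)$framed)
  expect_false(framing_test(0, 0)$framed)
  expect_true(is.na(framing_test(0, 0)$p_value))

  for (n in 1:20) for (k in 0:n)
    expect_equal(framing_test(n, k)$p_value, oracle_binom_upper(n, k),
                 tolerance = 1e-12, info = paste(n, k))
})

test_that("framing calls combine calibration and test per ORF and length", {
  cal <- calibrate_frames(data.frame(orf_id = "c", length = rep(c(30, 32), each = 3),
                                     frame = rep(0:2, 2),
                                     count = c(900, 50, 50, 50, 50, 900)))
  rt <- make_reads(list(list("t1", 60, 30, 8),       # all frame 0: framed
                        list("t1", 63, 32, 2),       # frame 0, expected is 2
                        list("t1", 64, 32, 2),
                        list("t1", 65, 32, 2)))
  prof <- assign_frames(rt, orf1)
  calls <- call_framing(prof, cal, stage = "Early", replica = "T")
  c30 <- calls[calls$length == 30, ]
  expect_true(c30$framed)
  expect_equal(c30[, c("n", "k")], data.frame(n = 8, k = 8),
               ignore_attr = TRUE)
  c32 <- calls[calls$length == 32, ]
  expect_equal(c32$k, 2)                              # only frame-2 reads
  expect_false(c32$framed)
})

test_that("translation events count distinct framed (length, replica, stage)", {
  calls <- data.frame(
    orf_id = "o1",
    length = c(30, 32, 30, 30, 28),
    replica = c("B", "B", "T", "B", "T"),
    stage = c("Early", "Early", "Mid", "Early", "Late"),
    framed = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # (30,B,Early) duplicated; unframed row ignored
  expect_equal(unname(count_translation_events(calls)), 3)
  calls$framed <- FALSE
  expect_equal(unname(count_translation_events(calls)), 0)
  # combinatorial maximum: 11 lengths x 2 replicas x 3 stages
  full <- expand.grid(length = 26:36, replica = c("T", "B"),
                      stage = c("Early", "Mid", "Late"))
  full$orf_id <- "o1"; full$framed <- TRUE
  expect_equal(unname(count_translation_events(full)), 66)
})

test_that("framing-pattern correlation behaves at the rank extremes", {
  base <- expand.grid(length = 26:36, frame = 0:2)
  base$orf_id <- "cls"
  base$count <- seq_len(nrow(base))
  expect_equal(framing_pattern_correlation(base, base), 1)
  rev_ <- base; rev_$count <- rev(base$count)
  expect_equal(framing_pattern_correlation(base, rev_), -1)
  flat <- base; flat$count <- 5
  expect_warning(r <- framing_pattern_correlation(base, flat), "zero-variance")
  expect_true(is.na(r))
  # independent uniform vectors: mean rho near 0
  set.seed(10)
  rhos <- replicate(200, {
    a <- base; a$count <- runif(33)
    b <- base; b$count <- runif(33)
    framing_pattern_correlation(a, b)
  })
  expect_lt(abs(mean(rhos)), 0.05)
})

test_that("null framing rate stays at the nominal level (type I)", {
  set.seed(77)
  n <- 30
  k <- rbinom(10000, n, 1/3)
  frac <- mean(framing_test(rep(n, 10000), k)$framed)
  expect_lte(frac, 0.01 + 3 * sqrt(0.01 * 0.99 / 10000))
})

test_that("framing power: fidelity 0.7 with 30 reads/length is detected", {
  set.seed(78)
  hits <- replicate(500, {
    any(vapply(1:11, function(i) {
      k <- rbinom(1, 30, 0.7)
      framing_test(30, k)$framed
    }, logical(1)))
  })
  expect_gte(mean(hits), 0.9)
})
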