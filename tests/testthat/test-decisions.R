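test_that("candidate flags follow the pNeg/pS threshold and data floor", {
  stats <- rbind(
    statRow("a", 1L, 300L, "+", 300L, 0.5),
    statRow("b", 400L, 700L, "+", 301L, 1.0),
    statRow("c", 800L, 1100L, "+", 301L, 1.01),
    statRow("d", 1200L, 1500L, "+", 301L, NA_real_),
    statRow("e", 1600L, 1900L, "+", 301L, Inf),
    statRow("f", 2000L, 2300L, "+", 301L, 0.2,
            flags = "insufficient_data"))
  out <- flagCandidates(stats, 3000L)
  expect_equal(MicroDiv:::.hasFlag(out$flags, "candidate"),
               c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("overprint candidates need overlap with a candidate in another frame", {
  # candidate gene, plus a nested ORF in a shifted frame with ratio 1.35
  stats <- rbind(
    statRow("gene", 100L, 1000L, "+", 901L, 0.4),
    statRow("nested", 301L, 601L, "+", 301L, 1.35, frame = 1L),
    statRow("lonely", 2000L, 2300L, "+", 301L, 1.35, frame = 1L))
  out <- flagCandidates(stats, 3000L)
  expect_true(MicroDiv:::.hasFlag(out$flags, "overprint_candidate")[2])
  expect_false(MicroDiv:::.hasFlag(out$flags, "overprint_candidate")[3])
  # same frame and strand never qualifies
  stats2 <- rbind(
    statRow("gene", 100L, 1000L, "+", 901L, 0.4),
    statRow("inframe", 400L, 700L, "+", 301L, 1.35))
  out2 <- flagCandidates(stats2, 3000L)
  expect_false(MicroDiv:::.hasFlag(out2$flags, "overprint_candidate")[2])
})

test_that("mirror candidates inside larger opposite-strand candidates are discarded", {
  stats <- rbind(
    statRow("A", 100L, 499L, "+", 400L, 0.4),
    statRow("B", 200L, 319L, "-", 120L, 0.8),
    statRow("C", 200L, 319L, "+", 120L, 0.8))   # same strand as A
  stats <- flagCandidates(stats, 1000L)
  out <- mirrorFilter(stats, 1000L)
  expect_true(MicroDiv:::.hasFlag(out$flags, "mirror_discarded")[2])
  expect_false(MicroDiv:::.hasFlag(out$flags, "candidate")[2])
  expect_equal(out$shadowed_by[2], "A")
  # same-strand containment is untouched
  expect_false(MicroDiv:::.hasFlag(out$flags, "mirror_discarded")[3])
  expect_true(MicroDiv:::.hasFlag(out$flags, "candidate")[3])
})

test_that("mirror tie-breaks are deterministic for equal-length pairs", {
  mk <- function(rA, rB) {
    s <- rbind(statRow("P", 100L, 399L, "+", 300L, rA),
               statRow("M", 100L, 399L, "-", 300L, rB))
    mirrorFilter(flagCandidates(s, 1000L), 1000L)
  }
  # higher ratio loses
  out <- mk(0.3, 0.9)
  expect_true(MicroDiv:::.hasFlag(out$flags, "mirror_discarded")[2])
  out <- mk(0.9, 0.3)
  expect_true(MicroDiv:::.hasFlag(out$flags, "mirror_discarded")[1])
  # ratio tie: the minus-strand ORF loses
  out <- mk(0.5, 0.5)
  expect_true(MicroDiv:::.hasFlag(out$flags, "mirror_discarded")[2])
  expect_false(MicroDiv:::.hasFlag(out$flags, "mirror_discarded")[1])
})

test_that("mirror filtering is idempotent and leaves no violating pair", {
  set.seed(42)
  for (rep in 1:10) {
    n <- 12L
    starts <- sample(1:800, n)
    lens <- sample(seq(90L, 450L, by = 3L), n, replace = TRUE)
    stats <- do.call(rbind, lapply(seq_len(n), function(i)
      statRow(sprintf("o%02d", i), starts[i],
              pmin(starts[i] + lens[i] - 1L, 1000L),
              sample(c("+", "-"), 1), lens[i],
              round(runif(1, 0, 1.4), 2))))
    stats$length_nt <- stats$end - stats$start + 1L
    stats <- flagCandidates(stats, 1000L)
    once <- mirrorFilter(stats, 1000L)
    twice <- mirrorFilter(once, 1000L)
    expect_identical(once, twice)
    # post-condition: no surviving candidate is contained (>= 90%) in a
    # larger surviving candidate on the opposite strand
    surv <- once[MicroDiv:::.hasFlag(once$flags, "candidate"), ]
    if (nrow(surv) > 1) {
      for (i in seq_len(nrow(surv))) for (j in seq_len(nrow(surv))) {
        if (i == j || surv$strand[i] == surv$strand[j]) next
        if (surv$length_nt[j] <= surv$length_nt[i]) next
        ov <- length(intersect(surv$start[i]:surv$end[i],
                               surv$start[j]:surv$end[j]))
        expect_lt(ov, 0.9 * surv$length_nt[i])
      }
    }
  }
})

test_that("lowering the candidate threshold never adds candidates", {
  set.seed(7)
  stats <- do.call(rbind, lapply(1:20, function(i)
    statRow(sprintf("o%02d", i), i * 40L, i * 40L + 119L, "+", 120L,
            round(runif(1, 0, 2), 2))))
  nCand <- function(thr)
    sum(MicroDiv:::.hasFlag(
      flagCandidates(stats, 2000L,
                     decisionConfig(candidate_max_ratio = thr))$flags,
      "candidate"))
  thrs <- c(0.2, 0.5, 0.8, 1.0, 1.3)
  counts <- vapply(thrs, nCand, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("the suspect-start rule needs a doubled 5' ratio and evidence", {
  mk <- function(whole, first50, n50)
    flagSuspectStart(statRow("v2", 1L, 360L, "+", 360L, whole,
                             first50 = first50, n_first50 = n50))
  # the worked case: 3.7 in the 5' window vs 0.57 whole-ORF
  expect_match(mk(0.57, 3.7, 6L)$flags, "suspect_start")
  # below the doubling threshold
  expect_false(grepl("suspect_start", mk(0.57, 1.0, 6L)$flags))
  # an infinite 5' ratio with thin evidence must not fire
  expect_false(grepl("suspect_start", mk(0.5, Inf, 1L)$flags))
  # whole-ORF ratio of zero disables the test
  expect_false(grepl("suspect_start", mk(0, 3.7, 6L)$flags))
  # undefined ratios disable the test
  expect_false(grepl("suspect_start", mk(NA_real_, 3.7, 6L)$flags))
})
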