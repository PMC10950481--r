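test_that("GC background splits composition between complementary bases", {
  expect_equal(background_from_gc(0.5)$p,
               c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  expect_equal(background_from_gc(0.6)$p,
               c(A = 0.2, C = 0.3, G = 0.3, T = 0.2))
  b <- background_from_gc(0.1234)
  expect_identical(unname(b$p["G"]), 0.1234 / 2)
  expect_identical(unname(b$p["A"]), (1 - 0.1234) / 2)
  expect_equal(sum(b$p), 1)
  expect_error(background_from_gc(0), "between 0 and 1")
  expect_error(background_from_gc(1), "between 0 and 1")
  expect_error(background_from_gc(-0.2), "between 0 and 1")
  expect_error(background_from_gc("0.5"), "between 0 and 1")
})

test_that("log2 scoring matrix matches direct ratios at uniform background", {
  col <- matrix(c(0.5, 0.25, 0.125, 0.125), 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  sm <- to_scoring_matrix(new_pwm("x", col), background_from_gc(0.5),
                          pseudocount = 0)
  expect_equal(unname(sm$scores[, 1]), c(1, 0, -1, -1))
  expect_equal(sm$max_score, 1)
  uni <- matrix(0.25, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  sm0 <- to_scoring_matrix(new_pwm("u", uni), background_from_gc(0.5),
                           pseudocount = 0)
  expect_equal(unname(sm0$scores), matrix(0, 4, 3))
})

test_that("every cell of a 2-column matrix at GC 0.4 equals the hand table", {
  # expected values recomputed cell by cell from the definition:
  # log2(p / background) with background A=T=0.3, C=G=0.2
  sm <- to_scoring_matrix(toy_pwm(), background_from_gc(0.4), pseudocount = 0)
  hand <- matrix(c(-1.584962500721156, 0.0, 0.584962500721156, 0.415037499278844,
                   -0.263034405833794, 0.321928094887362, 1.0, -1.584962500721156),
                 nrow = 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(sm$scores, hand, tolerance = 1e-12)
  expect_equal(sm$max_score, 0.584962500721156 + 1.0, tolerance = 1e-12)
})

test_that("pseudocount regularizes zeros; without it they are an error", {
  probs <- matrix(c(1, 0, 0, 0), 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- new_pwm("z", probs)
  expect_error(to_scoring_matrix(pwm, background_from_gc(0.5), pseudocount = 0),
               "degenerate")
  sm <- to_scoring_matrix(pwm, background_from_gc(0.5), pseudocount = 1e-3)
  expect_true(all(is.finite(sm$scores)))
  # regularized column: (P + pc) / (1 + 4 pc)
  expect_equal(unname(sm$scores["A", 1]), log2(((1 + 1e-3) / 1.004) / 0.25))
  expect_equal(unname(sm$scores["C", 1]), log2((1e-3 / 1.004) / 0.25))
})

test_that("at GC 0.5 the matrix is log2 of 4 times the regularized PWM", {
  pc <- 1e-3
  for (el in load_library()$elements) {
    sm <- to_scoring_matrix(el$pwm, background_from_gc(0.5), pseudocount = pc)
    expect_equal(sm$scores, log2(4 * (el$pwm$probs + pc) / (1 + 4 * pc)),
                 tolerance = 1e-9, info = el$name)
  }
})

test_that("raising GC lowers G/C scores and raises A/T scores monotonically", {
  pwm <- toy_pwm()
  gcs <- seq(0.2, 0.8, by = 0.1)
  mats <- lapply(gcs, function(g)
    to_scoring_matrix(pwm, background_from_gc(g), pseudocount = 0)$scores)
  for (i in seq_along(gcs)[-1]) {
    d <- mats[[i]] - mats[[i - 1]]
    expect_true(all(d[c("G", "C"), ] < 0))
    expect_true(all(d[c("A", "T"), ] > 0))
  }
})

test_that("window scoring: consensus, table lookups and the N rule", {
  sm <- to_scoring_matrix(toy_pwm(), background_from_gc(0.4), pseudocount = 0)
  expect_equal(score_window(sm, consensus_sequence(sm)), sm$max_score)
  # window "AC": cell (A, 1) + cell (C, 2), from the frozen hand table
  expect_equal(score_window(sm, "AC"),
               -1.584962500721156 + 0.321928094887362, tolerance = 1e-12)
  expect_equal(score_window(sm, "NN"), sum(apply(sm$scores, 2, min)))
  expect_equal(score_window(sm, "ac"), score_window(sm, "AC"))
  expect_error(score_window(sm, "ACG"), "length")
  expect_error(score_window(sm, "AX"), "outside")
})

test_that("the consensus window scores at least as high as every other window", {
  set.seed(11)
  pwm <- random_pwm("r3", 3L)
  sm <- to_scoring_matrix(pwm, background_from_gc(0.35))
  cons <- consensus_sequence(sm)
  all_windows <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 3)), 1,
                       paste0, collapse = "")
  scores <- vapply(all_windows, function(w) score_window(sm, w), 0)
  expect_equal(max(scores), score_window(sm, cons))
  expect_true(all(score_window(sm, cons) >= scores))
})

test_that("PWM files round-trip bit-exactly at 6 decimal digits", {
  pwm <- new_pwm("rt", matrix(c(0.123457, 0.2, 0.3, 0.376543,
                                0.25, 0.25, 0.25, 0.25), 4,
                              dimnames = list(c("A", "C", "G", "T"), NULL)),
                 anchor_offset = 1L, cutoff = 2.5)
  f1 <- tempfile(fileext = ".pwm"); f2 <- tempfile(fileext = ".pwm")
  write_pwm(pwm, f1)
  back <- read_pwm(f1)
  expect_identical(back$name, "rt")
  expect_identical(back$anchor_offset, 1L)
  expect_identical(back$cutoff, 2.5)
  expect_equal(back$probs, pwm$probs)
  write_pwm(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("structural invariants are enforced at construction and parse time", {
  bad <- matrix(c(0.4, 0.2, 0.2, 0.1, 0.25, 0.25, 0.25, 0.25), 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_error(new_pwm("bad", bad), "sums to 0.9")
  good <- matrix(0.25, 4, 2, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_error(new_pwm("bad", good, anchor_offset = 2L), "anchor_offset")
  expect_error(new_pwm("bad", good, anchor_offset = -1L), "anchor_offset")
  f <- tempfile(fileext = ".pwm")
  writeLines(c("#name=x anchor_offset=0 cutoff=0", "pos\t1",
               "A\t0.5", "C\t0.2", "G\t0.2", "T\t0.2"), f)
  expect_error(read_pwm(f), "sums to 1.1")
  writeLines(c("not a header", "pos\t1", "A\t1", "C\t0", "G\t0", "T\t0"), f)
  expect_error(read_pwm(f), "line 1")
})
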