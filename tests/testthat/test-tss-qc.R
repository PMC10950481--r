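hits_at <- function(pos, scores, element = "E", strand = "+") {
  data.frame(seq_id = sprintf("s%d", seq_along(pos)),
             element = rep_len(element, length(pos)),
             strand = rep_len(strand, length(pos)),
             start_tss_rel = as.integer(pos),
             anchor_tss_rel = as.integer(pos), score = scores,
             stringsAsFactors = FALSE)
}

test_that("a degenerate single-position distribution reports 100% with both score summaries", {
  d <- position_distribution(hits_at(rep(-2L, 10), 1:10), "E")
  expect_identical(nrow(d$table), 1L)
  expect_identical(d$table$position, -2L)
  expect_equal(d$table$fraction_pct, 100)
  expect_equal(d$table$mean_score, 5.5)
  expect_equal(d$table$median_score, 5.5)
  expect_identical(d$total_hits, 10L)
})

test_that("fractions are per-element shares that sum to 100", {
  d <- position_distribution(hits_at(c(-2, -2, -2, -1), c(1, 2, 3, 4)), "E")
  expect_equal(d$table$fraction_pct, c(75, 25))
  expect_identical(d$table$n_hits, c(3L, 1L))
  expect_equal(sum(d$table$fraction_pct), 100, tolerance = 1e-6)
  expect_identical(sum(d$table$n_hits), d$total_hits)
  # empty input: empty distribution, not an error
  e <- position_distribution(hits_at(integer(), numeric()), "E")
  expect_identical(nrow(e$table), 0L)
  expect_identical(e$total_hits, 0L)
})

test_that("hit order does not affect the distribution", {
  set.seed(5)
  h <- hits_at(sample(c(-3, -2, -2, 1, 5, 5, 5), 40, replace = TRUE),
               stats::rnorm(40))
  d1 <- position_distribution(h, "E")
  d2 <- position_distribution(h[sample(nrow(h)), ], "E")
  expect_equal(d1$table, d2$table)
})

test_that("planted motifs are recovered at their position from sampled instances", {
  lib <- load_library()
  sim <- generate_promoters(
    500, 201, 101, 0.4,
    specs = list(plant_spec("dInr", -2, probability = 0.6,
                            sample_from_pwm = TRUE)),
    seed = 424241, library = lib)
  res <- scan_pipeline(sim$records, lib, elements = "dInr", gc = 0.4)
  d <- position_distribution(res$hits, "dInr", axis = "tss")
  expect_identical(qc_summary(d)$modal_position, -2L)
})

test_that("qc summary: concentration is the ±2 share around the mode", {
  s1 <- qc_summary(position_distribution(hits_at(rep(4L, 7), 1:7), "E"))
  expect_equal(s1$concentration_pct, 100)
  expect_identical(s1$modal_position, 4L)
  # uniform over 20 contiguous positions: mode resolves centrally,
  # the ±2 window holds 5 of 20 positions -> 25%
  s2 <- qc_summary(position_distribution(hits_at(1:20, rep(1, 20)), "E"))
  expect_equal(s2$concentration_pct, 25)
  expect_equal(s2$modal_fraction_pct, 5)
})

test_that("the anchor axis uses composite spacing and drops orphans", {
  h <- hits_at(c(28, 28, 40), c(5, 6, 7), element = "DPE")
  h$spacing <- c(28L, 29L, NA)
  h$orphan_flag <- c(FALSE, FALSE, TRUE)
  h$composite_rule <- c("DPE<-dInr", "DPE<-dInr", NA)
  h$anchor_id <- c("dInr@+1", "dInr@+1", NA)
  d <- position_distribution(h, "DPE", axis = "anchor")
  expect_identical(d$total_hits, 2L)
  expect_identical(d$table$position, c(28L, 29L))
  expect_error(position_distribution(h[, 1:6], "DPE", axis = "anchor"),
               "composite")
})

test_that("positional jitter degrades concentration, and the comparison ranks it", {
  lib <- load_library()
  mk <- function(sd, seed) {
    sim <- generate_promoters(
      250, 201, 101, 0.45,
      specs = list(plant_spec("TATA", -31, probability = 0.8, jitter_sd = sd),
                   plant_spec("dInr", -2, probability = 0.8, jitter_sd = sd)),
      seed = seed, library = lib)
    res <- scan_pipeline(sim$records, lib, elements = c("TATA", "dInr"),
                         gc = 0.45)
    qc_summary(lapply(c("TATA", "dInr"), function(el)
      position_distribution(res$hits, el, axis = "tss")))
  }
  cmp <- compare_qc(list(sharp = mk(0, 77), smeared = mk(5, 78)))
  winners <- attr(cmp, "winners")
  expect_true(all(winners$dataset == "sharp"))
})

test_that("modal recovery under unit jitter stays within one position almost always", {
  lib <- load_library()
  sm <- library_scoring_matrices(lib, background_from_gc(0.45),
                                 elements = "dInr")
  ok <- 0L
  for (s in 1:100) {
    sim <- generate_promoters(
      120, 61, 31, 0.45,
      specs = list(plant_spec("dInr", -2, jitter_sd = 1)),
      seed = 20000 + s, library = lib)
    hits <- scan_sequences(sim$records, sm)
    m <- qc_summary(position_distribution(hits, "dInr"))$modal_position
    if (abs(m - (-2L)) <= 1L) ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})

test_that("distribution tables round-trip through the plot-ready TSV", {
  f <- tempfile(fileext = ".tsv")
  export_distribution_table(list(), f)
  empty <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("element", "position", "fraction_pct", "mean_score",
                    "median_score", "n_hits") %in% names(empty)))
  d1 <- position_distribution(hits_at(rep(-2L, 10), 1:10), "E")
  set.seed(12)
  d2 <- position_distribution(
    hits_at(sample(-5:5, 60, replace = TRUE), stats::rnorm(60),
            element = "E2"), "E2")
  export_distribution_table(list(d1, d2), f)
  tab <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_identical(nrow(tab[tab$element == "E", ]), 1L)
  expect_equal(tab$fraction_pct[tab$element == "E"], 100)
  back <- read_distribution_table(f)
  expect_length(back, 2)
  expect_equal(back$E.tss$table, d1$table, tolerance = 1e-9)
  expect_equal(back$E2.tss$table, d2$table, tolerance = 1e-9)
  expect_identical(back$E2.tss$total_hits, d2$total_hits)
})
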