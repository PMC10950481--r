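# shared fixtures and the independent brute-force scanning oracle

# 2-column PWM with hand-checkable probabilities
toy_pwm <- function(cutoff = -Inf, anchor_offset = 0L) {
  probs <- matrix(c(0.1, 0.2, 0.3, 0.4,
                    0.25, 0.25, 0.4, 0.1), nrow = 4,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
  new_pwm("toy", probs, anchor_offset = anchor_offset, cutoff = cutoff)
}

# strongly peaked single-consensus PWM from a plain DNA string
peaked_pwm <- function(name, consensus, anchor_offset = 0L, cutoff = -Inf,
                       peak = 0.91) {
  bases <- strsplit(consensus, "", fixed = TRUE)[[1]]
  probs <- vapply(bases, function(b) {
    p <- rep((1 - peak) / 3, 4)
    names(p) <- c("A", "C", "G", "T")
    p[b] <- peak
    p
  }, numeric(4))
  rownames(probs) <- c("A", "C", "G", "T")
  new_pwm(name, probs, anchor_offset = anchor_offset, cutoff = cutoff)
}

# random probability matrix (columns Dirichlet-ish via normalized uniforms)
random_pwm <- function(name, L, cutoff = -Inf, anchor_offset = 0L) {
  probs <- matrix(stats::runif(4 * L, min = 0.05), nrow = 4)
  probs <- sweep(probs, 2, colSums(probs), "/")
  rownames(probs) <- c("A", "C", "G", "T")
  new_pwm(name, probs, anchor_offset = anchor_offset, cutoff = cutoff)
}

random_records <- function(n, min_len, max_len, with_n = FALSE) {
  alph <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  lens <- sample(min_len:max_len, n, replace = TRUE)
  seqs <- vapply(lens, function(l)
    paste0(sample(alph, l, replace = TRUE), collapse = ""), "")
  seq_records(sprintf("r%03d", seq_len(n)), seqs,
              tss_index = pmax(1L, lens %/% 2L))
}

# reverse complement written independently of the package
rc_chartr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# brute-force enumeration of every window on every strand: the oracle the
# scanner is checked against; scores each window by direct cell lookup
oracle_scan <- function(records, matrices, strands = "both") {
  if (inherits(matrices, "scoring_matrix")) matrices <- list(matrices)
  rows <- list(); k <- 0L
  for (r in seq_len(nrow(records))) {
    s <- records$seq[r]
    n <- nchar(s)
    tss <- records$tss_index[r]
    for (sm in matrices) {
      L <- ncol(sm$scores)
      if (n < L) next
      colmin <- apply(sm$scores, 2, min)
      score_str <- function(str) {
        b <- strsplit(str, "", fixed = TRUE)[[1]]
        tot <- 0
        for (j in seq_len(L))
          tot <- tot + if (b[j] == "N") colmin[j] else sm$scores[b[j], j]
        tot
      }
      for (i in seq_len(n - L + 1L)) {
        w <- substr(s, i, i + L - 1L)
        sc <- score_str(w)
        if (sc >= sm$cutoff) {
          k <- k + 1L
          rows[[k]] <- data.frame(
            seq_id = records$id[r], element = sm$name, strand = "+",
            start_abs = i, end_abs = i + L - 1L,
            start_tss_rel = tss_relative(i, tss),
            anchor_tss_rel = tss_relative(i + sm$anchor_offset, tss),
            score = sc, stringsAsFactors = FALSE)
        }
        if (strands == "both") {
          sc2 <- score_str(rc_chartr(w))
          if (sc2 >= sm$cutoff) {
            k <- k + 1L
            five <- i + L - 1L
            rows[[k]] <- data.frame(
              seq_id = records$id[r], element = sm$name, strand = "-",
              start_abs = i, end_abs = i + L - 1L,
              start_tss_rel = tss_relative(five, tss),
              anchor_tss_rel = tss_relative(five - sm$anchor_offset, tss),
              score = sc2, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- if (k) do.call(rbind, rows) else
    data.frame(seq_id = character(), element = character(), strand = character(),
               start_abs = integer(), end_abs = integer(),
               start_tss_rel = integer(), anchor_tss_rel = integer(),
               score = numeric(), stringsAsFactors = FALSE)
  sort_hits(out)
}

sort_hits <- function(h) {
  h <- h[order(h$seq_id, h$start_abs, h$element, h$strand), , drop = FALSE]
  rownames(h) <- NULL
  h
}

expect_same_hits <- function(got, want, tol = 1e-9) {
  got <- sort_hits(got[, names(want), drop = FALSE])
  want <- sort_hits(want)
  expect_equal(nrow(got), nrow(want))
  for (cl in setdiff(names(want), "score"))
    expect_identical(got[[cl]], want[[cl]])
  expect_equal(got$score, want$score, tolerance = tol)
}
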