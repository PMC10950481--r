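#!/usr/bin/env Rscript
# Regenerates the bundled element library under inst/extdata/elements/.
#
# The matrices are consensus-derived reconstructions: each element's IUPAC
# consensus is expanded column-wise with fixed degeneracy weights (every
# disallowed base gets 0.02; the allowed bases share the remainder equally),
# rounded to 6 decimals with a largest-entry adjustment so columns sum to
# exactly 1.000000. Default cutoffs are 60% of each matrix's maximal score at
# uniform background (GC 0.5, pseudocount 1e-3), rounded to 3 decimals.
#
# Run from the package root:  Rscript tools/make_builtin_pwms.R

pkgload::load_all(".", quiet = TRUE)

IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

consensus_column <- function(ch) {
  allowed <- IUPAC[[ch]]
  p <- stats::setNames(rep(0.02, 4), c("A", "C", "G", "T"))
  p[allowed] <- (1 - 0.02 * (4 - length(allowed))) / length(allowed)
  if (length(allowed) == 4L) p[] <- 0.25
  p <- round(p, 6)
  p[which.max(p)] <- p[which.max(p)] + (1 - sum(p))  # exact column sum
  p
}

consensus_pwm <- function(name, consensus, anchor_offset) {
  cols <- strsplit(consensus, "", fixed = TRUE)[[1]]
  probs <- vapply(cols, consensus_column, numeric(4))
  rownames(probs) <- c("A", "C", "G", "T")
  pwm <- new_pwm(name, probs, anchor_offset = anchor_offset)
  sm <- to_scoring_matrix(pwm, background_from_gc(0.5), pseudocount = 1e-3)
  pwm$cutoff <- round(0.6 * sm$max_score, 3)
  pwm
}

defs <- list(
  list("TATA",     "TATAWAWR",         0L, "upstream",   c(-36L, -24L),
       "TATA box consensus"),
  list("Inr",      "YYANWYY",          2L, "initiator",  c(-4L, 4L),
       "human initiator consensus; A+1 at motif offset 2"),
  list("dInr",     "TCAGTY",           2L, "initiator",  c(-4L, 4L),
       "Drosophila initiator consensus; A+1 at motif offset 2"),
  list("BBCA+1BW", "BBCABW",           3L, "initiator",  c(-5L, 4L),
       "BBCA+1BW initiator consensus; A+1 at motif offset 3"),
  list("DPE",      "RGWYV",            0L, "downstream", c(24L, 35L),
       "downstream promoter element consensus; functional at +28..+33 from initiator A+1"),
  list("MTE",      "CSARCSSAACGS",     0L, "downstream", c(15L, 28L),
       "motif ten element consensus"),
  list("BREu",     "SSRCGCC",          0L, "upstream",   c(-40L, -30L),
       "TFIIB recognition element, upstream of the TATA box"),
  list("BREd",     "RTDKKKK",          0L, "upstream",   c(-26L, -17L),
       "TFIIB recognition element, downstream of the TATA box"),
  list("TCT",      "YYCTTTYY",         2L, "initiator",  c(-4L, 4L),
       "human polypyrimidine (TCT) initiator; C+1 at motif offset 2"),
  list("dTCT",     "YYCTTTYY",         2L, "initiator",  c(-4L, 4L),
       "Drosophila polypyrimidine (TCT) initiator; C+1 at motif offset 2"),
  list("Bridge",   "CGANCNNNNNNNGCGW", 0L, "downstream", c(15L, 35L),
       "bipartite bridge element, coarse single-matrix form (uninformative spacer columns)"),
  list("PB",       "KCGRWCG",          0L, "pausing",    c(20L, 32L),
       "pause button, Pol II pausing-associated downstream motif"),
  list("Motif1",   "YGGTCACACTR",      0L, "pausing",    c(-10L, 1L),
       "Ohler motif 1, promoter-proximal pausing-associated motif"),
  list("GAGA",     "GAGAG",            0L, "pausing",    NULL,
       "GAGA factor binding site (GAGAG repeat, CIS-BP M5247-style)"))

out_dir <- file.path("inst", "extdata", "elements")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

meta <- list()
for (d in defs) {
  pwm <- consensus_pwm(d[[1]], d[[2]], d[[3]])
  write_pwm(pwm, file.path(out_dir, paste0(d[[1]], ".pwm")))
  meta[[d[[1]]]] <- c(list(category = d[[4]]),
                      if (!is.null(d[[5]])) list(window = d[[5]]),
                      list(citation = d[[6]]))
}

rules <- list()
for (dep in c("DPE", "MTE", "Bridge")) {
  win <- switch(dep, DPE = c(28L, 33L), MTE = c(18L, 22L), Bridge = c(18L, 33L))
  for (anchor in c("dInr", "Inr"))
    rules[[length(rules) + 1L]] <- list(dependent = dep, anchor = anchor,
                                        min_spacing = win[1], max_spacing = win[2])
}

yaml::write_yaml(list(elements = meta, rules = rules),
                 file.path(out_dir, "rules.yaml"))
cat("wrote", length(defs), "matrices and", length(rules), "rules to", out_dir, "\n")
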