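DNA_BASES <- c("A", "C", "G", "T")

#' Background nucleotide model from GC content
#'
#' Builds a zero-order background model in which the supplied GC fraction is
#' split evenly between G and C, and the AT remainder evenly between A and T:
#' \eqn{p_G = p_C = GC/2}, \eqn{p_A = p_T = (1-GC)/2}. This is the background
#' used to normalize position weight matrices before log2-likelihood scoring,
#' so that composition bias of the input sequences does not masquerade as
#' motif signal.
#'
#' @param gc GC fraction, strictly between 0 and 1. The open interval is
#'   enforced because a zero background probability makes the log2 ratio
#'   undefined.
#' @return An object of class \code{background_model}: a list with elements
#'   \code{gc} and \code{p} (named probabilities for A, C, G, T summing to 1).
#' @examples
#' background_from_gc(0.5)$p   # uniform
#' background_from_gc(0.6)$p   # G=C=0.3, A=T=0.2
#' @export
background_from_gc <- function(gc) {
  if (!is.numeric(gc) || length(gc) != 1L || is.na(gc) || gc <= 0 || gc >= 1) {
    stop("invalid parameter: gc must be a single number strictly between 0 and 1 (got ",
         deparse(gc), "); a GC fraction of exactly 0 or 1 gives a zero ",
         "background probability and an undefined log2 score", call. = FALSE)
  }
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  structure(list(gc = gc, p = p), class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("Background model (GC = %.4f)\n", x$gc))
  print(round(x$p, 6))
  invisible(x)
}

#' Construct a position weight matrix
#'
#' A PWM is a 4 x L matrix of per-position nucleotide probabilities (rows A,
#' C, G, T), together with the metadata needed to scan and report it: an
#' anchor offset marking the biologically functional base of the motif (for
#' an initiator, the A+1 base) and a minimal reportable log2 score.
#'
#' @param name Element identifier (no whitespace).
#' @param probs 4 x L numeric matrix; rows must be A, C, G, T (rownames are
#'   set if missing) and every column must sum to 1 within 1e-6.
#' @param anchor_offset 0-based offset, within the motif, of the anchor base.
#'   All anchor-relative spacing (e.g. of a DPE from an initiator A+1) is
#'   measured from this base, not from the motif start.
#' @param cutoff Minimal log2 score (bits) at which a window is reported as a
#'   hit; hits are reported when score >= cutoff.
#' @return Object of class \code{pwm}.
#' @export
new_pwm <- function(name, probs, anchor_offset = 0L, cutoff = -Inf) {
  probs <- as.matrix(probs)
  if (is.null(rownames(probs))) rownames(probs) <- DNA_BASES
  x <- structure(
    list(name = as.character(name), probs = probs,
         anchor_offset = as.integer(anchor_offset), cutoff = as.numeric(cutoff)),
    class = "pwm")
  validate_pwm(x)
  x
}

#' Validate a PWM object
#'
#' Checks the structural invariants: a 4 x L matrix with rows A/C/G/T, all
#' probabilities non-negative, every column summing to 1 within 1e-6, and an
#' anchor offset inside the motif.
#'
#' @param pwm A \code{pwm} object.
#' @param tol Column-sum tolerance.
#' @return The object, invisibly; stops with an informative error otherwise.
#' @export
validate_pwm <- function(pwm, tol = 1e-6) {
  p <- pwm$probs
  if (!is.matrix(p) || nrow(p) != 4L || ncol(p) < 1L)
    stop("PWM '", pwm$name, "': probs must be a 4 x L matrix", call. = FALSE)
  if (!identical(rownames(p), DNA_BASES))
    stop("PWM '", pwm$name, "': rows must be A, C, G, T in that order", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0))
    stop("PWM '", pwm$name, "': probabilities must be finite and >= 0", call. = FALSE)
  cs <- colSums(p)
  bad <- which(abs(cs - 1) > tol)
  if (length(bad))
    stop(sprintf("PWM '%s': column %d sums to %.6f, not 1 (tolerance %g)",
                 pwm$name, bad[1L], cs[bad[1L]], tol), call. = FALSE)
  if (is.na(pwm$anchor_offset) || pwm$anchor_offset < 0L ||
      pwm$anchor_offset >= ncol(p))
    stop("PWM '", pwm$name, "': anchor_offset must lie in [0, L)", call. = FALSE)
  invisible(pwm)
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s': %d positions, anchor_offset=%d, cutoff=%s\n",
              x$name, ncol(x$probs), x$anchor_offset, format(x$cutoff)))
  print(round(x$probs, 4))
  invisible(x)
}

#' Convert a PWM to a log2-likelihood scoring matrix
#'
#' Every cell becomes \eqn{score(i,j) = \log_2(\tilde P(i,j) / p_i)}, where
#' \eqn{p_i} is the background probability of nucleotide i (GC/2 for G and C,
#' (1-GC)/2 for A and T) and \eqn{\tilde P} is the PWM regularized by an
#' additive pseudocount renormalized per column,
#' \eqn{\tilde P = (P + pc) / (1 + 4\,pc)}. The pseudocount guards against
#' \code{log2(0)} for matrices containing zero probabilities while leaving
#' consensus rankings intact at its small default.
#'
#' @param pwm A \code{pwm}.
#' @param bg A \code{background_model} from [background_from_gc()].
#' @param pseudocount Additive pseudocount applied before the log (default
#'   1e-3). With 0, any zero probability in the PWM is an error.
#' @return Object of class \code{scoring_matrix}: the 4 x L score matrix in
#'   bits, its \code{max_score} (sum of per-column maxima), and the
#'   \code{anchor_offset} and \code{cutoff} carried over from the PWM.
#' @examples
#' pwm <- new_pwm("toy", matrix(c(0.5, 0.25, 0.125, 0.125), 4, 1,
#'                              dimnames = list(c("A","C","G","T"), NULL)))
#' to_scoring_matrix(pwm, background_from_gc(0.5), pseudocount = 0)$scores
#' @export
to_scoring_matrix <- function(pwm, bg, pseudocount = 1e-3) {
  validate_pwm(pwm)
  stopifnot(inherits(bg, "background_model"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0)
    stop("pseudocount must be a single number >= 0", call. = FALSE)
  probs <- (pwm$probs + pseudocount) / (1 + 4 * pseudocount)
  if (any(probs == 0))
    stop("degenerate matrix: PWM '", pwm$name, "' contains zero probabilities ",
         "and pseudocount is 0; log2 scores would be -Inf", call. = FALSE)
  scores <- log2(probs / bg$p[rownames(probs)])
  max_score <- sum(apply(scores, 2L, max))
  if (is.finite(pwm$cutoff) && max_score < pwm$cutoff)
    warning(sprintf("PWM '%s': max_score %.3f is below its cutoff %.3f; no window can ever be reported",
                    pwm$name, max_score, pwm$cutoff), call. = FALSE)
  structure(
    list(name = pwm$name, scores = scores, max_score = max_score,
         anchor_offset = pwm$anchor_offset, cutoff = pwm$cutoff,
         gc = bg$gc, pseudocount = pseudocount),
    class = "scoring_matrix")
}

#' @export
print.scoring_matrix <- function(x, ...) {
  cat(sprintf(
    "Scoring matrix '%s' (bits, GC=%.3f): L=%d, max_score=%.3f, cutoff=%s\n",
    x$name, x$gc, ncol(x$scores), x$max_score, format(round(x$cutoff, 3))))
  print(round(x$scores, 3))
  invisible(x)
}

#' Score a single sequence window against a scoring matrix
#'
#' Sums the per-position log2 scores of the window's bases. An N contributes
#' the column minimum, so ambiguous bases can only suppress a hit, never
#' create one.
#'
#' @param sm A \code{scoring_matrix}.
#' @param window DNA string whose length equals the matrix width; alphabet
#'   A, C, G, T, N (case-insensitive).
#' @return Log2 score in bits.
#' @export
score_window <- function(sm, window) {
  stopifnot(inherits(sm, "scoring_matrix"))
  L <- ncol(sm$scores)
  window <- toupper(window)
  if (!is.character(window) || length(window) != 1L || nchar(window) != L)
    stop("invalid input: window must be a single string of length ", L, call. = FALSE)
  idx <- match(strsplit(window, "", fixed = TRUE)[[1L]], c(DNA_BASES, "N"))
  if (anyNA(idx))
    stop("invalid input: window contains characters outside {A,C,G,T,N}", call. = FALSE)
  s5 <- rbind(sm$scores, apply(sm$scores, 2L, min))
  sum(s5[cbind(idx, seq_len(L))])
}

#' Consensus sequence of a matrix
#'
#' The highest-probability (or highest-scoring) base per column; ties resolve
#' to the earlier base in A, C, G, T order.
#'
#' @param x A \code{pwm} or \code{scoring_matrix}.
#' @return A string of length L.
#' @export
consensus_sequence <- function(x) {
  m <- if (inherits(x, "pwm")) x$probs else x$scores
  paste0(DNA_BASES[apply(m, 2L, which.max)], collapse = "")
}

#' Read a PWM file
#'
#' Parses the tab-delimited PWM text format: a first line
#' \code{#name=<element> anchor_offset=<k> cutoff=<x>}, a header row
#' \code{pos 1 .. L}, and four probability rows labeled A, C, G, T. The
#' reader/writer pair round-trips bit-exactly at 6 decimal digits.
#'
#' @param path Path to a PWM file.
#' @return A \code{pwm} object.
#' @seealso [write_pwm()]
#' @export
read_pwm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 6L)
    stop("PWM parse error in '", path, "': expected a header line, a position row and four base rows",
         call. = FALSE)
  hdr <- lines[1L]
  if (!startsWith(hdr, "#name="))
    stop("PWM parse error in '", path, "', line 1: first line must start with '#name='",
         call. = FALSE)
  fields <- strsplit(sub("^#", "", hdr), "[[:space:]]+")[[1L]]
  kv <- strsplit(fields, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L))
    stop("PWM parse error in '", path, "', line 1: header fields must be key=value",
         call. = FALSE)
  meta <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  for (req in c("name", "anchor_offset", "cutoff"))
    if (!req %in% names(meta))
      stop("PWM parse error in '", path, "', line 1: missing '", req, "='", call. = FALSE)
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  lab <- vapply(rows, `[`, "", 1L)
  if (lab[1L] != "pos")
    stop("PWM parse error in '", path, "', line 2: expected 'pos' header row", call. = FALSE)
  if (!identical(lab[2:5], DNA_BASES))
    stop("PWM parse error in '", path, "': expected rows A, C, G, T after the header",
         call. = FALSE)
  vals <- lapply(rows[2:5], function(r) suppressWarnings(as.numeric(r[-1L])))
  L <- length(rows[[1L]]) - 1L
  if (any(lengths(vals) != L) || anyNA(unlist(vals)))
    stop("PWM parse error in '", path, "': base rows must each hold ", L,
         " numeric probabilities", call. = FALSE)
  probs <- do.call(rbind, vals)
  rownames(probs) <- DNA_BASES
  new_pwm(meta[["name"]], probs,
          anchor_offset = as.integer(meta[["anchor_offset"]]),
          cutoff = as.numeric(meta[["cutoff"]]))
}

#' Write a PWM file
#'
#' Inverse of [read_pwm()]; probabilities are written with 6 decimal digits.
#'
#' @param pwm A \code{pwm}.
#' @param path Output path.
#' @param digits Decimal digits for probabilities (default 6).
#' @return \code{path}, invisibly.
#' @export
write_pwm <- function(pwm, path, digits = 6L) {
  validate_pwm(pwm)
  L <- ncol(pwm$probs)
  hdr <- sprintf("#name=%s anchor_offset=%d cutoff=%s",
                 pwm$name, pwm$anchor_offset,
                 if (is.finite(pwm$cutoff)) format(pwm$cutoff, trim = TRUE) else
                   as.character(pwm$cutoff))
  posrow <- paste(c("pos", seq_len(L)), collapse = "\t")
  baserows <- vapply(DNA_BASES, function(b)
    paste(c(b, formatC(pwm$probs[b, ], format = "f", digits = digits)),
          collapse = "\t"), "")
  writeLines(c(hdr, posrow, baserows), path)
  invisible(path)
}
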