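#' TSS-relative coordinates
#'
#' Converts a 1-based position within a sequence to the biology-style axis in
#' which the TSS base is +1 and there is no position 0: the base immediately
#' 5' of the TSS is -1. This is the axis on which element positions such as a
#' dInr at -2 or a pause button at +26 are conventionally reported.
#'
#' @param pos 1-based position(s) within the sequence.
#' @param tss_index 1-based index of the TSS base.
#' @return Integer TSS-relative coordinate(s); never 0.
#' @seealso [tss_absolute()] for the inverse mapping.
#' @export
tss_relative <- function(pos, tss_index) {
  as.integer(ifelse(pos >= tss_index, pos - tss_index + 1L, pos - tss_index))
}

#' @rdname tss_relative
#' @param rel TSS-relative coordinate(s); 0 is invalid.
#' @export
tss_absolute <- function(rel, tss_index) {
  if (any(rel == 0L, na.rm = TRUE))
    stop("TSS-relative coordinate 0 does not exist on this axis", call. = FALSE)
  as.integer(ifelse(rel > 0L, tss_index + rel - 1L, tss_index + rel))
}

#' Assemble sequence records
#'
#' Normalizes inputs into the record table the scanner consumes: one row per
#' sequence with its identifier, uppercased sequence and the 1-based index of
#' the TSS base. Records shorter than their TSS index are rejected with a
#' named warning; alphabet is restricted to A, C, G, T, N after uppercasing.
#'
#' @param id Character vector of sequence identifiers.
#' @param seq Character vector of DNA sequences.
#' @param tss_index 1-based TSS position, recycled across records, or one
#'   value per record.
#' @param mask_lower Treat soft-masked (lowercase) bases as N instead of as
#'   normal bases.
#' @return data.frame with columns \code{id}, \code{seq}, \code{tss_index}.
#' @export
seq_records <- function(id, seq, tss_index, mask_lower = FALSE) {
  stopifnot(length(id) == length(seq))
  if (anyDuplicated(id))
    stop("duplicate sequence ids: ", paste(unique(id[duplicated(id)]), collapse = ", "),
         call. = FALSE)
  if (mask_lower) seq <- gsub("[acgtn]", "N", seq)
  seq <- toupper(seq)
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad))
    stop("invalid input: sequence '", id[which(bad)[1L]],
         "' contains characters outside {A,C,G,T,N}", call. = FALSE)
  tss_index <- as.integer(rep_len(tss_index, length(id)))
  short <- tss_index < 1L | tss_index > nchar(seq)
  if (any(short)) {
    warning("rejected record(s) with tss_index outside the sequence: ",
            paste(id[short], collapse = ", "), call. = FALSE)
    id <- id[!short]; seq <- seq[!short]; tss_index <- tss_index[!short]
  }
  data.frame(id = as.character(id), seq = seq, tss_index = tss_index,
             stringsAsFactors = FALSE)
}

# encode a sequence as integers A=1 C=2 G=3 T=4 N=5
encode_seq <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1L]], c(DNA_BASES, "N"))
}

# reverse-complement on the integer encoding (N stays N)
revcomp_idx <- function(idx) {
  out <- rev(idx)
  nn <- out == 5L
  out <- 5L - out
  out[nn] <- 5L
  out
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string over A, C, G, T, N (case-insensitive).
#' @return Reverse-complemented uppercase string.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

# slide one scoring matrix (with N row appended) over one encoded sequence;
# returns numeric vector of window scores, windows indexed by leftmost base
slide_scores <- function(s5, idx) {
  L <- ncol(s5)
  n_win <- length(idx) - L + 1L
  sc <- numeric(n_win)
  for (j in seq_len(L)) sc <- sc + s5[idx[j:(j + n_win - 1L)], j]
  sc
}

empty_hits <- function() {
  data.frame(seq_id = character(), element = character(), strand = character(),
             start_abs = integer(), end_abs = integer(),
             start_tss_rel = integer(), anchor_tss_rel = integer(),
             score = numeric(), stringsAsFactors = FALSE)
}

#' Scan sequences for motif hits
#'
#' Slides every scoring matrix over every record and reports each window
#' whose log2 score is greater than or equal to the matrix cutoff — all
#' passing hits, not only the best per sequence. With \code{strands =
#' "both"}, the reverse complement of each sequence is scanned as well;
#' an antisense hit is reported with strand \code{"-"}, its coordinates
#' given on the + strand of the input sequence.
#'
#' Coordinates: \code{start_tss_rel} is the TSS-relative position of the
#' hit's 5'-most base (for a - strand hit, that base sits at the right end of
#' the occupied + strand interval); \code{anchor_tss_rel} is the TSS-relative
#' position of the motif's anchor base (e.g. the A+1 of an initiator).
#' \code{start_abs}/\code{end_abs} are the 1-based + strand bounds of the
#' occupied interval, strand-independent, for interval exports.
#'
#' @param records data.frame from [seq_records()] or [read_fasta_records()].
#' @param matrices A \code{scoring_matrix}, or list of them.
#' @param strands \code{"both"} (default) or \code{"sense"}.
#' @return data.frame of hits ordered by (seq_id, position, element):
#'   columns seq_id, element, strand, start_abs, end_abs, start_tss_rel,
#'   anchor_tss_rel, score.
#' @examples
#' pwm <- new_pwm("toy", matrix(c(.97,.01,.01,.01, .01,.01,.97,.01), 4, 2,
#'                dimnames = list(c("A","C","G","T"), NULL)), cutoff = 0)
#' sm <- to_scoring_matrix(pwm, background_from_gc(0.5))
#' recs <- seq_records("s1", "NNAGNN", tss_index = 3)
#' scan_sequences(recs, sm)
#' @export
scan_sequences <- function(records, matrices, strands = c("both", "sense")) {
  strands <- match.arg(strands)
  if (inherits(matrices, "scoring_matrix")) matrices <- list(matrices)
  if (!length(matrices)) stop("at least one scoring matrix is required", call. = FALSE)
  stopifnot(all(vapply(matrices, inherits, TRUE, "scoring_matrix")))
  out <- list()
  k <- 0L
  for (r in seq_len(nrow(records))) {
    idx <- encode_seq(records$seq[r])
    n <- length(idx)
    tss <- records$tss_index[r]
    ridx <- if (strands == "both") revcomp_idx(idx) else NULL
    for (sm in matrices) {
      L <- ncol(sm$scores)
      if (n < L) {
        warning("sequence '", records$id[r], "' (", n,
                " bp) is shorter than matrix '", sm$name, "' (", L,
                " bp); skipped", call. = FALSE)
        next
      }
      s5 <- rbind(sm$scores, apply(sm$scores, 2L, min))
      sc <- slide_scores(s5, idx)
      pass <- which(sc >= sm$cutoff)
      if (length(pass)) {
        left <- pass
        k <- k + 1L
        out[[k]] <- data.frame(
          seq_id = records$id[r], element = sm$name, strand = "+",
          start_abs = left, end_abs = left + L - 1L,
          start_tss_rel = tss_relative(left, tss),
          anchor_tss_rel = tss_relative(left + sm$anchor_offset, tss),
          score = sc[pass], stringsAsFactors = FALSE)
      }
      if (strands == "both") {
        scm <- slide_scores(s5, ridx)
        pass <- which(scm >= sm$cutoff)
        if (length(pass)) {
          # window at rc offset j occupies + strand bases (n-j-L+2)..(n-j+1);
          # its 5'-most base (on the - strand) is + strand base n-j+1
          j <- pass
          left <- n - j - L + 2L
          five <- n - j + 1L
          anchor <- n - (j + sm$anchor_offset) + 1L
          k <- k + 1L
          out[[k]] <- data.frame(
            seq_id = records$id[r], element = sm$name, strand = "-",
            start_abs = left, end_abs = left + L - 1L,
            start_tss_rel = tss_relative(five, tss),
            anchor_tss_rel = tss_relative(anchor, tss),
            score = scm[pass], stringsAsFactors = FALSE)
        }
      }
    }
  }
  hits <- if (k) do.call(rbind, out) else empty_hits()
  hits <- hits[order(hits$seq_id, hits$start_abs, hits$element, hits$strand), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}
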