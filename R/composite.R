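ANNOT_COLS <- c("composite_rule", "anchor_id", "spacing", "orphan_flag")

# offset of pos from ref along the direction of transcription, on the
# skip-zero axis where the reference base itself is +1
anchored_offset <- function(pos, ref, strand) {
  n <- max(length(pos), length(ref), length(strand))
  pos <- rep_len(pos, n)
  ref <- rep_len(ref, n)
  strand <- rep_len(strand, n)
  d <- ifelse(strand == "+", pos - ref, ref - pos)
  as.integer(ifelse(d >= 0L, d + 1L, d))
}

#' Call composite core promoter elements
#'
#' A downstream element such as the DPE is only functional when an initiator
#' is present at precise spacing from its A+1 base. This applies that
#' dependency to a raw hit table: for every hit of a dependent element, the
#' qualifying anchors are the hits of the rule's initiator on the same
#' sequence and strand whose A+1 base places the dependent's start inside the
#' rule's spacing window. Spacing is measured on the skip-zero anchor axis
#' where the A+1 base itself is +1, so a DPE starting 27 bp 3' of the A+1 has
#' spacing +28.
#'
#' One call is made per dependent hit (not all pairs): among qualifying
#' anchors the one with the highest score wins, ties broken by smallest
#' distance of the spacing from the window midpoint, then by anchor
#' position. Dependent hits with no qualifying anchor are flagged orphan and
#' retained — they stay visible to positional-distribution reports, just
#' down-weighted by the flag.
#'
#' @param hits Hit data.frame from [scan_sequences()] (or re-read from TSV);
#'   any previous composite annotation columns are recomputed, making the
#'   operation idempotent.
#' @param rules data.frame with columns dependent, anchor, min_spacing,
#'   max_spacing — e.g. \code{load_library()$rules}.
#' @return List with \code{hits} (input plus columns composite_rule,
#'   anchor_id, spacing, orphan_flag) and \code{calls} (one row per composite
#'   call: rule, anchor and dependent coordinates, spacing, combined score =
#'   anchor score + dependent score).
#' @export
call_composites <- function(hits, rules) {
  hits <- hits[, setdiff(names(hits), ANNOT_COLS), drop = FALSE]
  n <- nrow(hits)
  hits$composite_rule <- NA_character_
  hits$anchor_id <- NA_character_
  hits$spacing <- NA_integer_
  hits$orphan_flag <- NA
  calls <- list(); ck <- 0L
  if (n && nrow(rules)) {
    dep_elements <- unique(rules$dependent)
    is_dep <- hits$element %in% dep_elements
    hits$orphan_flag[is_dep] <- TRUE
    grp <- interaction(hits$seq_id, hits$strand, drop = TRUE)
    for (g in split(seq_len(n), grp)) {
      for (di in g[hits$element[g] %in% dep_elements]) {
        dep <- hits[di, ]
        dep_abs <- tss_absolute(dep$start_tss_rel, 10000000L)
        rls <- rules[rules$dependent == dep$element, , drop = FALSE]
        # gather qualifying anchors over all rules for this dependent element
        cand <- list(); cn <- 0L
        for (ri in seq_len(nrow(rls))) {
          ai <- g[hits$element[g] == rls$anchor[ri]]
          if (!length(ai)) next
          a_abs <- tss_absolute(hits$anchor_tss_rel[ai], 10000000L)
          sp <- anchored_offset(dep_abs, a_abs, dep$strand)
          ok <- sp >= rls$min_spacing[ri] & sp <= rls$max_spacing[ri]
          if (any(ok)) {
            cn <- cn + 1L
            cand[[cn]] <- data.frame(
              ai = ai[ok], spacing = sp[ok],
              mid = (rls$min_spacing[ri] + rls$max_spacing[ri]) / 2,
              rule_anchor = rls$anchor[ri], stringsAsFactors = FALSE)
          }
        }
        if (!cn) next
        cand <- do.call(rbind, cand)
        cand$a_score <- hits$score[cand$ai]
        cand$a_pos <- hits$anchor_tss_rel[cand$ai]
        o <- order(-cand$a_score, abs(cand$spacing - cand$mid), cand$a_pos)
        best <- cand[o[1L], ]
        a <- hits[best$ai, ]
        rule_id <- paste0(dep$element, "<-", best$rule_anchor)
        hits$composite_rule[di] <- rule_id
        hits$anchor_id[di] <- sprintf("%s@%+d", a$element, a$anchor_tss_rel)
        hits$spacing[di] <- best$spacing
        hits$orphan_flag[di] <- FALSE
        ck <- ck + 1L
        calls[[ck]] <- data.frame(
          seq_id = dep$seq_id, rule = rule_id, strand = dep$strand,
          anchor_element = a$element, anchor_tss_rel = a$anchor_tss_rel,
          anchor_score = a$score, dependent_element = dep$element,
          dependent_start_tss_rel = dep$start_tss_rel,
          dependent_score = dep$score, spacing = best$spacing,
          combined_score = a$score + dep$score, stringsAsFactors = FALSE)
      }
    }
  }
  calls <- if (ck) do.call(rbind, calls) else
    data.frame(seq_id = character(), rule = character(), strand = character(),
               anchor_element = character(), anchor_tss_rel = integer(),
               anchor_score = numeric(), dependent_element = character(),
               dependent_start_tss_rel = integer(), dependent_score = numeric(),
               spacing = integer(), combined_score = numeric(),
               stringsAsFactors = FALSE)
  calls <- calls[order(calls$seq_id, calls$dependent_start_tss_rel, calls$rule), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  rownames(hits) <- NULL
  list(hits = hits, calls = calls)
}
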