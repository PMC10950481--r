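#' Specify a motif to plant in synthetic promoters
#'
#' Describes one planted element for [generate_promoters()]: which element,
#' where, how reliably, and with how much positional scatter. The target
#' position is given on the skip-zero TSS axis (position of the motif's first
#' base; \code{axis = "tss"}) or, for initiator-dependent elements, on the
#' anchor axis — the motif start's offset from the A+1 base of an anchor
#' initiator planted in the same sequence (\code{axis = "anchor"}, with
#' \code{anchor_element} naming that initiator; sequences in which the anchor
#' was not planted fall back to the TSS base as the reference).
#'
#' @param element Element name (must exist in the library handed to the
#'   generator).
#' @param position Target position on the chosen axis (no position 0).
#' @param probability Per-sequence planting probability in [0, 1].
#' @param jitter_sd Standard deviation of the discrete, symmetric positional
#'   jitter (integer positions; 0 = exact placement). Instances jittered
#'   beyond the sequence bounds are skipped and logged.
#' @param sample_from_pwm Plant a PWM-sampled instance instead of the
#'   consensus.
#' @param anchor_element Anchor initiator name; required when
#'   \code{axis = "anchor"}.
#' @param axis \code{"tss"} or \code{"anchor"}.
#' @return Object of class \code{plant_spec}.
#' @export
plant_spec <- function(element, position, probability = 1, jitter_sd = 0,
                       sample_from_pwm = FALSE, axis = c("tss", "anchor"),
                       anchor_element = NULL) {
  axis <- match.arg(axis)
  stopifnot(probability >= 0, probability <= 1, jitter_sd >= 0, position != 0)
  if (axis == "anchor" && is.null(anchor_element))
    stop("axis 'anchor' requires anchor_element", call. = FALSE)
  structure(list(element = element, position = as.integer(position),
                 probability = probability, jitter_sd = jitter_sd,
                 sample_from_pwm = sample_from_pwm, axis = axis,
                 anchor_element = anchor_element),
            class = "plant_spec")
}

#' Generate synthetic promoter sequences with planted motifs
#'
#' Builds fixed-width promoter windows whose background bases are i.i.d. from
#' the GC-derived background model, then plants each specified motif
#' independently per sequence with its probability at its target position
#' plus jitter. This emulates the positional structure of real TSS-centered
#' windows — an initiator at the TSS, a downstream element at fixed spacing,
#' scatter controlled per element — so that scanning, composite calling and
#' positional QC are all testable without external data. Overlapping plants
#' are resolved later-spec-wins, and the overlap is recorded in the ground
#' truth. Plants are placed on the + strand.
#'
#' @param n Number of sequences.
#' @param width Sequence width in bp (must accommodate the longest plant).
#' @param tss_index 1-based TSS position within each window (101 for a
#'   ±100 bp window of width 201).
#' @param gc Background GC fraction in (0, 1).
#' @param specs List of [plant_spec()] objects (possibly empty).
#' @param seed Mandatory integer seed; the same seed reproduces the output
#'   byte for byte. The caller's RNG state is left untouched.
#' @param library Element library supplying the PWMs; default the bundled one.
#' @return Object of class \code{promoter_sim}: \code{records} (data.frame
#'   id, seq, tss_index), \code{truth} (one row per planted instance: seq_id,
#'   element, axis, target_position, realized_position, start_abs,
#'   instance_seq, overlapped) and \code{n_skipped} (instances lost to the
#'   sequence bounds).
#' @export
generate_promoters <- function(n, width, tss_index, gc, specs = list(),
                               seed, library = NULL) {
  if (missing(seed)) stop("seed is mandatory for reproducibility", call. = FALSE)
  if (inherits(specs, "plant_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, TRUE, "plant_spec")),
            n >= 1, width >= 1, tss_index >= 1, tss_index <= width)
  if (is.null(library) && length(specs)) library <- load_library()
  pwms <- lapply(specs, function(s) {
    if (!s$element %in% names(library$elements))
      stop("plant spec names unknown element '", s$element, "'", call. = FALSE)
    library$elements[[s$element]]$pwm
  })
  too_long <- vapply(pwms, function(p) ncol(p$probs), 0L) > width
  if (any(too_long))
    stop("width ", width, " is shorter than planted motif '",
         specs[[which(too_long)[1L]]]$element, "'", call. = FALSE)

  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  bg <- background_from_gc(gc)
  mat <- matrix(sample(DNA_BASES, n * width, replace = TRUE, prob = bg$p),
                nrow = n, ncol = width)
  ids <- sprintf("synth_%0*d", nchar(n), seq_len(n))

  truth <- list(); tk <- 0L; n_skipped <- 0L
  for (i in seq_len(n)) {
    planted_at <- integer(0)       # per planted instance: start_abs
    planted_end <- integer(0)
    planted_row <- integer(0)      # index into truth
    anchor_a1 <- list()            # realized A+1 abs position per element
    for (si in seq_along(specs)) {
      s <- specs[[si]]
      if (stats::runif(1) > s$probability) next
      pwm <- pwms[[si]]
      L <- ncol(pwm$probs)
      jitter <- if (s$jitter_sd > 0) as.integer(round(stats::rnorm(1, 0, s$jitter_sd))) else 0L
      if (s$axis == "anchor") {
        ref <- if (!is.null(anchor_a1[[s$anchor_element]]))
          anchor_a1[[s$anchor_element]] else tss_index
        # skip-zero offset from the reference base: offset +1 is the ref itself
        start_abs <- ref + ifelse(s$position > 0, s$position - 1L, s$position) + jitter
      } else {
        ref <- NA_integer_
        start_abs <- tss_absolute(s$position, tss_index) + jitter
      }
      if (start_abs < 1L || start_abs + L - 1L > width) {
        n_skipped <- n_skipped + 1L
        message("skipped out-of-bounds plant of ", s$element, " in ", ids[i])
        next
      }
      inst <- if (s$sample_from_pwm) {
        vapply(seq_len(L), function(j)
          sample(DNA_BASES, 1L, prob = pwm$probs[, j]), "")
      } else {
        DNA_BASES[apply(pwm$probs, 2L, which.max)]
      }
      span <- start_abs:(start_abs + L - 1L)
      # later-spec-wins: mark earlier instances whose bases we overwrite
      if (length(planted_at)) {
        clobbered <- which(planted_at <= span[L] & planted_end >= span[1L])
        for (p in clobbered) truth[[planted_row[p]]]$overlapped <- TRUE
      }
      mat[i, span] <- inst
      if (pwm$anchor_offset >= 0L)
        anchor_a1[[s$element]] <- start_abs + pwm$anchor_offset
      tk <- tk + 1L
      truth[[tk]] <- data.frame(
        seq_id = ids[i], element = s$element, axis = s$axis,
        target_position = s$position,
        realized_position = if (s$axis == "anchor")
          anchored_offset(start_abs, ref, "+")
        else tss_relative(start_abs, tss_index),
        start_abs = start_abs, instance_seq = paste0(inst, collapse = ""),
        overlapped = FALSE, stringsAsFactors = FALSE)
      planted_at <- c(planted_at, start_abs)
      planted_end <- c(planted_end, start_abs + L - 1L)
      planted_row <- c(planted_row, tk)
    }
  }
  truth <- if (tk) do.call(rbind, truth) else
    data.frame(seq_id = character(), element = character(), axis = character(),
               target_position = integer(), realized_position = integer(),
               start_abs = integer(), instance_seq = character(),
               overlapped = logical(), stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  records <- data.frame(id = ids, seq = apply(mat, 1L, paste0, collapse = ""),
                        tss_index = as.integer(tss_index),
                        stringsAsFactors = FALSE)
  structure(list(records = records, truth = truth, n_skipped = n_skipped,
                 gc = gc, seed = seed),
            class = "promoter_sim")
}

#' @export
print.promoter_sim <- function(x, ...) {
  cat(sprintf("Synthetic promoter set: %d sequences x %d bp (TSS at column %d, GC %.2f, seed %s)\n",
              nrow(x$records), nchar(x$records$seq[1L]), x$records$tss_index[1L],
              x$gc, format(x$seed)))
  cat(sprintf("  %d planted instances (%d skipped at bounds)\n",
              nrow(x$truth), x$n_skipped))
  invisible(x)
}

#' Write a synthetic promoter set to disk
#'
#' Emits standard-format FASTA plus a separate ground-truth TSV (the truth is
#' never encoded only in FASTA headers, so the FASTA stays a plain fixture).
#'
#' @param sim A \code{promoter_sim}.
#' @param prefix Output prefix; writes \code{<prefix>.fa} and
#'   \code{<prefix>.truth.tsv}.
#' @return Character vector of the two paths, invisibly.
#' @export
write_promoter_sim <- function(sim, prefix) {
  stopifnot(inherits(sim, "promoter_sim"))
  fa <- paste0(prefix, ".fa")
  tr <- paste0(prefix, ".truth.tsv")
  dna <- Biostrings::DNAStringSet(stats::setNames(sim$records$seq,
                                                  sim$records$id))
  Biostrings::writeXStringSet(dna, fa)
  utils::write.table(sim$truth, tr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fa, truth = tr))
}
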