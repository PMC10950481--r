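#' Positional distribution of an element's hits
#'
#' For one element, tabulates where its hits fall and how well they score
#' there: per occupied position, the number of hits, the fraction (%) of all
#' hits of that element found at that position (so fractions sum to 100%
#' over the element), and the mean and median log2 score. Tight, high-scoring
#' positional preferences — a Drosophila initiator at -2, a DPE at +28 on the
#' anchor axis — are the signature of a well-determined TSS dataset, which is
#' what these distributions are used to appraise.
#'
#' Two reporting axes exist. \code{axis = "tss"} bins hits by the
#' TSS-relative position of the motif start (\code{start_tss_rel}), the axis
#' on which upstream elements and initiators are conventionally plotted.
#' \code{axis = "anchor"} bins composite-dependent hits by their spacing from
#' the anchor initiator's A+1 (the \code{spacing} column produced by
#' [call_composites()]); orphan hits carry no spacing and are excluded on
#' this axis.
#'
#' @param hits Hit data.frame ([scan_sequences()], optionally composite
#'   annotated).
#' @param element Element name to tabulate.
#' @param axis \code{"tss"} (default) or \code{"anchor"}.
#' @return Object of class \code{positional_distribution}: element, axis,
#'   \code{table} (position, n_hits, fraction_pct, mean_score, median_score,
#'   sorted by position) and \code{total_hits}. An element with no hits
#'   yields an empty table, not an error.
#' @export
position_distribution <- function(hits, element, axis = c("tss", "anchor")) {
  axis <- match.arg(axis)
  h <- hits[hits$element == element, , drop = FALSE]
  if (axis == "anchor") {
    if (!"spacing" %in% names(h))
      stop("axis 'anchor' requires composite-annotated hits (spacing column); ",
           "run call_composites() first", call. = FALSE)
    h <- h[!is.na(h$spacing), , drop = FALSE]
    pos <- h$spacing
  } else {
    pos <- h$start_tss_rel
  }
  if (!nrow(h)) {
    tab <- data.frame(position = integer(), n_hits = integer(),
                      fraction_pct = numeric(), mean_score = numeric(),
                      median_score = numeric())
  } else {
    sp <- split(h$score, pos)
    upos <- as.integer(names(sp))
    o <- order(upos)
    sp <- sp[o]; upos <- upos[o]
    n_hits <- lengths(sp)
    tab <- data.frame(
      position = upos, n_hits = as.integer(n_hits),
      fraction_pct = 100 * n_hits / nrow(h),
      mean_score = vapply(sp, mean, 0),
      median_score = vapply(sp, stats::median, 0), row.names = NULL)
  }
  structure(list(element = element, axis = axis, table = tab,
                 total_hits = nrow(h)),
            class = "positional_distribution")
}

#' @export
print.positional_distribution <- function(x, ...) {
  cat(sprintf("Positional distribution of %s (%s axis): %d hits over %d positions\n",
              x$element, x$axis, x$total_hits, nrow(x$table)))
  if (nrow(x$table)) {
    tt <- x$table
    tt$fraction_pct <- round(tt$fraction_pct, 2)
    tt$mean_score <- round(tt$mean_score, 3)
    tt$median_score <- round(tt$median_score, 3)
    print(utils::head(tt[order(-tt$fraction_pct), ], 10L), row.names = FALSE)
  }
  invisible(x)
}

# modal position with ties broken by the (lower) median tied position, so a
# flat stretch of tied maxima reports its central position rather than an edge
modal_position <- function(tab) {
  mx <- max(tab$fraction_pct)
  tied <- tab$position[tab$fraction_pct >= mx - 1e-9]
  sort(tied)[ceiling(length(tied) / 2)]
}

#' Summarize positional distributions for TSS quality control
#'
#' Reduces each distribution to the quantities used to judge how sharply an
#' element is positioned: the modal position (most frequent position; ties
#' resolve to the central tied position), the fraction of hits at the mode,
#' and the positional concentration — the fraction of all hits within ±2
#' positions of the mode, with unoccupied positions counting zero. Sharper
#' concentration of elements with strict spacing requirements indicates more
#' precisely determined TSSs.
#'
#' @param distributions A \code{positional_distribution} or list of them.
#' @return data.frame with one row per element: element, axis, total_hits,
#'   modal_position, modal_fraction_pct, concentration_pct.
#' @export
qc_summary <- function(distributions) {
  if (inherits(distributions, "positional_distribution"))
    distributions <- list(distributions)
  stopifnot(length(distributions) >= 1L)
  rows <- lapply(distributions, function(d) {
    stopifnot(inherits(d, "positional_distribution"))
    if (!nrow(d$table))
      return(data.frame(element = d$element, axis = d$axis, total_hits = 0L,
                        modal_position = NA_integer_,
                        modal_fraction_pct = NA_real_,
                        concentration_pct = NA_real_, stringsAsFactors = FALSE))
    tab <- d$table
    mode <- modal_position(tab)
    near <- abs(tab$position - mode) <= 2L
    data.frame(element = d$element, axis = d$axis, total_hits = d$total_hits,
               modal_position = mode,
               modal_fraction_pct = max(tab$fraction_pct),
               concentration_pct = sum(tab$fraction_pct[near]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare datasets by positional concentration
#'
#' Ranks TSS datasets element-by-element: the dataset whose hits are more
#' concentrated around each element's modal position is the one whose TSS
#' calls better respect that element's natural spacing preference. This is
#' the miniature of comparing, say, nascent-transcription-derived TSSs
#' against 5'-tag-derived ones.
#'
#' @param summaries Named list of [qc_summary()] data.frames, one per dataset.
#' @return data.frame in long format (element, axis, dataset,
#'   concentration_pct, rank within element with 1 = most concentrated) plus
#'   an attribute \code{"winners"}: per element, the top-ranked dataset.
#' @export
compare_qc <- function(summaries) {
  stopifnot(is.list(summaries), length(summaries) >= 2L,
            !is.null(names(summaries)), all(nzchar(names(summaries))))
  long <- do.call(rbind, lapply(names(summaries), function(ds) {
    s <- summaries[[ds]]
    data.frame(element = s$element, axis = s$axis, dataset = ds,
               concentration_pct = s$concentration_pct, stringsAsFactors = FALSE)
  }))
  key <- paste(long$element, long$axis)
  long$rank <- stats::ave(-ifelse(is.na(long$concentration_pct), -Inf,
                                  long$concentration_pct),
                          key, FUN = rank)
  long <- long[order(long$element, long$rank), ]
  rownames(long) <- NULL
  winners <- do.call(rbind, lapply(split(long, paste(long$element, long$axis)),
                                   function(x) x[which.min(x$rank), c("element", "axis", "dataset")]))
  rownames(winners) <- NULL
  attr(long, "winners") <- winners
  long
}

#' Export positional distributions as a plot-ready table
#'
#' Long-format TSV with one row per element x position: element, axis,
#' position, n_hits, fraction_pct, mean_score, median_score — the data matrix
#' behind heat-colored positional bar plots (bar height = fraction, color =
#' mean score).
#'
#' @param distributions List of \code{positional_distribution} objects (an
#'   empty list writes a header-only file).
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
export_distribution_table <- function(distributions, path) {
  if (inherits(distributions, "positional_distribution"))
    distributions <- list(distributions)
  cols <- c("element", "axis", "position", "n_hits", "fraction_pct",
            "mean_score", "median_score")
  rows <- lapply(distributions, function(d) {
    if (!nrow(d$table)) return(NULL)
    cbind(data.frame(element = d$element, axis = d$axis,
                     stringsAsFactors = FALSE), d$table)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write distribution table to '", path, "': ",
         conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  utils::write.table(format(out[, cols], digits = 15, trim = TRUE,
                            scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a distribution table
#'
#' Inverse of [export_distribution_table()]: reconstructs the
#' \code{positional_distribution} objects from the TSV.
#'
#' @param path TSV path.
#' @return Named list of \code{positional_distribution} objects (name =
#'   \code{element.axis}).
#' @export
read_distribution_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!nrow(tab)) return(list())
  out <- lapply(split(tab, paste(tab$element, tab$axis, sep = ".")), function(x) {
    x <- x[order(x$position), ]
    structure(list(
      element = x$element[1L], axis = x$axis[1L],
      table = data.frame(position = as.integer(x$position),
                         n_hits = as.integer(x$n_hits),
                         fraction_pct = x$fraction_pct,
                         mean_score = x$mean_score,
                         median_score = x$median_score, row.names = NULL),
      total_hits = sum(x$n_hits)), class = "positional_distribution")
  })
  out
}
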