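ELEMENT_CATEGORIES <- c("initiator", "upstream", "downstream", "pausing", "user")

#' Element libraries
#'
#' An element library bundles a set of core promoter element definitions —
#' each a PWM plus its category, the TSS-relative window where the element is
#' biologically expected (metadata only, never a hard filter) and a citation —
#' together with the composite rules connecting downstream elements to their
#' initiator anchors.
#'
#' The bundled default library covers TATA, the human initiator (Inr), the
#' Drosophila initiator (dInr), the BBCA+1BW initiator, DPE, MTE, BREu, BREd,
#' the human and Drosophila TCT initiators, Bridge, the pause button (PB),
#' Ohler Motif1 and the GAGA factor binding site. Its matrices are
#' consensus-derived reconstructions (see the package vignette), not
#' transcriptions of any published matrix download, and its cutoffs are
#' conservative defaults.
#'
#' @param dir Directory containing one \code{.pwm} file per element and a
#'   \code{rules.yaml} with categories, expected windows, citations and
#'   composite rules. \code{NULL} (default) loads the bundled library.
#' @return Object of class \code{element_library}: list with \code{elements}
#'   (named list of element definitions) and \code{rules} (data.frame with
#'   columns dependent, anchor, min_spacing, max_spacing).
#' @export
load_library <- function(dir = NULL) {
  if (is.null(dir)) dir <- system.file("extdata", "elements", package = "corescan")
  if (!dir.exists(dir)) stop("library directory not found: ", dir, call. = FALSE)
  files <- sort(list.files(dir, pattern = "\\.pwm$", full.names = TRUE))
  if (!length(files)) warning("empty library: no .pwm files in ", dir, call. = FALSE)
  pwms <- lapply(files, read_pwm)
  names(pwms) <- vapply(pwms, `[[`, "", "name")
  if (anyDuplicated(names(pwms)))
    stop("duplicate element names in library: ",
         paste(unique(names(pwms)[duplicated(names(pwms))]), collapse = ", "),
         call. = FALSE)
  meta <- list(); rules <- empty_rules()
  yml_path <- file.path(dir, "rules.yaml")
  if (file.exists(yml_path)) {
    yml <- yaml::read_yaml(yml_path)
    meta <- if (!is.null(yml$elements)) yml$elements else list()
    if (!is.null(yml$rules) && length(yml$rules)) {
      rules <- do.call(rbind, lapply(yml$rules, function(r)
        data.frame(dependent = r$dependent, anchor = r$anchor,
                   min_spacing = as.integer(r$min_spacing),
                   max_spacing = as.integer(r$max_spacing),
                   stringsAsFactors = FALSE)))
    }
  }
  elements <- lapply(names(pwms), function(nm) {
    m <- meta[[nm]]
    new_element(
      pwm = pwms[[nm]],
      category = if (!is.null(m$category)) m$category else "user",
      default_search_window = if (!is.null(m$window)) as.integer(m$window) else NULL,
      citation = if (!is.null(m$citation)) m$citation else "")
  })
  names(elements) <- names(pwms)
  lib <- structure(list(elements = elements, rules = rules),
                   class = "element_library")
  validate_library(lib)
  lib
}

empty_rules <- function() {
  data.frame(dependent = character(), anchor = character(),
             min_spacing = integer(), max_spacing = integer(),
             stringsAsFactors = FALSE)
}

new_element <- function(pwm, category, default_search_window = NULL, citation = "") {
  category <- match.arg(category, ELEMENT_CATEGORIES)
  structure(list(name = pwm$name, pwm = pwm, category = category,
                 default_search_window = default_search_window,
                 citation = citation),
            class = "element_definition")
}

#' Validate an element library
#'
#' Checks referential integrity of the composite rules (every rule names
#' elements present in the library; every anchor is an initiator) and
#' non-empty spacing windows. PWM-level invariants are checked per matrix at
#' read time.
#'
#' @param lib An \code{element_library}.
#' @return The library, invisibly.
#' @export
validate_library <- function(lib) {
  stopifnot(inherits(lib, "element_library"))
  nms <- names(lib$elements)
  r <- lib$rules
  if (nrow(r)) {
    missing <- setdiff(c(r$dependent, r$anchor), nms)
    if (length(missing))
      stop("composite rule references unknown element(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    cat_of <- vapply(lib$elements, `[[`, "", "category")
    bad <- r$anchor[cat_of[r$anchor] != "initiator"]
    if (length(bad))
      stop("composite rule anchor(s) not of category 'initiator': ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    if (any(r$max_spacing < r$min_spacing))
      stop("composite rule with empty spacing window", call. = FALSE)
  }
  invisible(lib)
}

#' @export
print.element_library <- function(x, ...) {
  cat(sprintf("Element library: %d elements, %d composite rules\n",
              length(x$elements), nrow(x$rules)))
  for (e in x$elements)
    cat(sprintf("  %-10s %-10s L=%-3d cutoff=%-8s %s\n", e$name, e$category,
                ncol(e$pwm$probs), format(round(e$pwm$cutoff, 3)),
                if (is.null(e$default_search_window)) "" else
                  sprintf("expected %+d..%+d", e$default_search_window[1],
                          e$default_search_window[2])))
  if (nrow(x$rules))
    for (i in seq_len(nrow(x$rules)))
      cat(sprintf("  rule: %s anchored to %s A+1 at %+d..%+d\n",
                  x$rules$dependent[i], x$rules$anchor[i],
                  x$rules$min_spacing[i], x$rules$max_spacing[i]))
  invisible(x)
}

#' Write an element library to a directory
#'
#' One \code{.pwm} file per element plus \code{rules.yaml}; inverse of
#' [load_library()], round-tripping bit-exactly at 6 decimal digits.
#'
#' @param lib An \code{element_library}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_library <- function(lib, dir) {
  validate_library(lib)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list()
  for (e in lib$elements) {
    write_pwm(e$pwm, file.path(dir, paste0(e$name, ".pwm")))
    meta[[e$name]] <- list(category = e$category, citation = e$citation)
    if (!is.null(e$default_search_window))
      meta[[e$name]]$window <- as.integer(e$default_search_window)
  }
  rules <- if (nrow(lib$rules)) lapply(seq_len(nrow(lib$rules)), function(i)
    list(dependent = lib$rules$dependent[i], anchor = lib$rules$anchor[i],
         min_spacing = lib$rules$min_spacing[i],
         max_spacing = lib$rules$max_spacing[i])) else list()
  yaml::write_yaml(list(elements = meta, rules = rules),
                   file.path(dir, "rules.yaml"))
  invisible(dir)
}

#' Add a user-defined motif to a library
#'
#' The motif is registered with category \code{user} and is scanned
#' identically to the built-in elements.
#'
#' @param lib An \code{element_library}.
#' @param pwm A \code{pwm} object, or path to a PWM file.
#' @param default_search_window Optional expected TSS-relative window
#'   (metadata only).
#' @param citation Optional provenance string.
#' @return The updated library.
#' @export
add_user_motif <- function(lib, pwm, default_search_window = NULL, citation = "") {
  stopifnot(inherits(lib, "element_library"))
  if (is.character(pwm)) pwm <- read_pwm(pwm)
  validate_pwm(pwm)
  if (pwm$name %in% names(lib$elements))
    stop("name conflict: element '", pwm$name, "' already present in the library",
         call. = FALSE)
  lib$elements[[pwm$name]] <- new_element(pwm, "user", default_search_window,
                                          citation)
  lib
}

#' Scoring matrices for library elements
#'
#' Converts the selected elements' PWMs to log2-likelihood scoring matrices
#' under one background, applying any cutoff overrides.
#'
#' @param lib An \code{element_library}.
#' @param bg A \code{background_model}.
#' @param elements Character vector of element names to include; \code{NULL}
#'   for all.
#' @param cutoff_overrides Named numeric vector of per-element cutoffs
#'   replacing the library defaults.
#' @param pseudocount Passed to [to_scoring_matrix()].
#' @return Named list of \code{scoring_matrix} objects.
#' @export
library_scoring_matrices <- function(lib, bg, elements = NULL,
                                     cutoff_overrides = NULL,
                                     pseudocount = 1e-3) {
  stopifnot(inherits(lib, "element_library"))
  if (is.null(elements)) elements <- names(lib$elements)
  unknown <- setdiff(elements, names(lib$elements))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  out <- lapply(elements, function(nm) {
    pwm <- lib$elements[[nm]]$pwm
    if (!is.null(cutoff_overrides) && nm %in% names(cutoff_overrides))
      pwm$cutoff <- as.numeric(cutoff_overrides[[nm]])
    to_scoring_matrix(pwm, bg, pseudocount = pseudocount)
  })
  stats::setNames(out, elements)
}
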