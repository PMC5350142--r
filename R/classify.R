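# Phylogroup assignment from marker presence/absence patterns, mixed-sample
# deconvolution, exhaustive pattern enumeration, and the accuracy accounting
# used to summarize large-scale in-silico validation.

#' Construct a marker pattern
#'
#' An observed presence/absence vector for one sample. Markers listed in
#' neither set are untested (allowed for deconvolution, not for isolate
#' classification).
#'
#' @param sample_id Sample label.
#' @param present Marker ids observed positive.
#' @param absent Marker ids observed negative.
#' @return A list of class `marker_pattern`.
#' @export
marker_pattern <- function(sample_id, present = character(0),
                           absent = character(0)) {
  present <- unique(as.character(present))
  absent <- unique(as.character(absent))
  both <- intersect(present, absent)
  if (length(both)) {
    stop("marker(s) both present and absent: ", paste(both, collapse = ", "),
         call. = FALSE)
  }
  structure(list(sample_id = as.character(sample_id), present = present,
                 absent = absent),
            class = "marker_pattern")
}

#' @export
print.marker_pattern <- function(x, ...) {
  cat("pattern", x$sample_id, "| present: {",
      paste(sort(x$present), collapse = ", "), "}\n")
  invisible(x)
}

check_pattern_panel <- function(pattern, matrix) {
  ids <- rownames(matrix)
  unknown <- setdiff(c(pattern$present, pattern$absent), ids)
  if (length(unknown)) {
    stop("pattern references marker(s) outside the panel: ",
         paste(unknown, collapse = ", "),
         "; panel markers are ", paste(ids, collapse = ", "), call. = FALSE)
  }
  invisible(ids)
}

group_conflicts <- function(group, present, matrix) {
  req <- required_markers(matrix, group)
  forb <- forbidden_markers(matrix, group)
  missing <- setdiff(req, present)
  hit_forb <- intersect(forb, present)
  rbind(
    if (length(missing)) {
      data.frame(group = group, marker = missing,
                 reason = "required marker absent", stringsAsFactors = FALSE)
    },
    if (length(hit_forb)) {
      data.frame(group = group, marker = hit_forb,
                 reason = "forbidden marker present", stringsAsFactors = FALSE)
    }
  )
}

#' Classify an isolate's marker pattern
#'
#' Assigns a phylogroup to a fully tested isolate: the assigned group is the
#' unique group whose required markers are all present and none of whose
#' forbidden markers is present (variable markers are unconstrained),
#' subject to at least `min_positive` positive reactions overall. Patterns
#' matching no group -- including the single stray positive seen in
#' out-of-complex controls -- return `"none"` with the near-miss conflicts
#' recorded.
#'
#' In `"lenient"` mode a pattern that matches no group strictly is given the
#' best-scoring group (most required markers present, penalized for missing
#' required and present forbidden markers) with its conflicts listed; this
#' is intended for triaging noisy data and never alters strict assignments.
#'
#' @param pattern A [marker_pattern()] covering the full panel.
#' @param matrix Decision matrix, as in [builtin_panel()].
#' @param min_positive Minimum positive reactions backing an assignment.
#' @param mode `"strict"` (default) or `"lenient"`.
#' @return A list of class `phylogroup_call`: `sample_id`, `assigned_group`
#'   (`"none"` if unassigned), `supporting_markers`, `conflicts` (data
#'   frame), `n_positive`, `mode`.
#' @examples
#' panel <- builtin_panel()
#' classify_pattern(
#'   marker_pattern("F113", present = c("DGPf_0", "DGPf_1"),
#'                  absent = paste0("DGPf_", 2:8)),
#'   panel$matrix
#' )
#' @export
classify_pattern <- function(pattern, matrix, min_positive = 2,
                             mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  ids <- check_pattern_panel(pattern, matrix)
  untested <- setdiff(ids, c(pattern$present, pattern$absent))
  if (length(untested)) {
    stop("isolate classification needs the full panel tested; marker(s) ",
         paste(untested, collapse = ", "), " are untested. ",
         "Use deconvolve_pattern() for partial or pooled patterns.",
         call. = FALSE)
  }
  present <- pattern$present
  groups <- colnames(matrix)
  strict_ok <- vapply(groups, function(g) {
    all(required_markers(matrix, g) %in% present) &&
      !any(forbidden_markers(matrix, g) %in% present)
  }, logical(1))
  n_pos <- length(present)
  conflicts <- do.call(rbind, c(
    lapply(groups[!strict_ok], group_conflicts, present = present,
           matrix = matrix),
    list(make.row.names = FALSE)
  ))
  if (is.null(conflicts)) {
    conflicts <- data.frame(group = character(0), marker = character(0),
                            reason = character(0), stringsAsFactors = FALSE)
  }
  assigned <- "none"
  if (n_pos >= min_positive) {
    hit <- groups[strict_ok]
    if (length(hit) > 1) {
      stop("ambiguous decision matrix: pattern matches groups ",
           paste(hit, collapse = ", "),
           " -- run validate_panel() on this panel", call. = FALSE)
    }
    if (length(hit) == 1) assigned <- hit
  }
  if (assigned == "none" && mode == "lenient" && n_pos >= 1) {
    score <- vapply(groups, function(g) {
      req <- required_markers(matrix, g)
      forb <- forbidden_markers(matrix, g)
      length(intersect(req, present)) - length(setdiff(req, present)) -
        length(intersect(forb, present))
    }, numeric(1))
    assigned <- groups[which.max(score)]  # ties: first in panel column order
  }
  supporting <- if (assigned == "none") character(0) else {
    intersect(present, c(required_markers(matrix, assigned),
                         variable_markers(matrix, assigned)))
  }
  structure(list(sample_id = pattern$sample_id, assigned_group = assigned,
                 supporting_markers = supporting, conflicts = conflicts,
                 n_positive = n_pos, mode = mode),
            class = "phylogroup_call")
}

#' @export
print.phylogroup_call <- function(x, ...) {
  cat(sprintf("%s -> %s (%d positive reaction%s%s)\n", x$sample_id,
              x$assigned_group, x$n_positive,
              if (x$n_positive == 1) "" else "s",
              if (length(x$supporting_markers)) {
                paste0("; supported by ",
                       paste(sort(x$supporting_markers), collapse = ", "))
              } else ""))
  invisible(x)
}

#' Deconvolve a pooled (community) marker pattern
#'
#' For metagenomic or otherwise mixed DNA, the observed pattern is the union
#' of the patterns of the taxa present. A phylogroup is *compatible* with
#' the sample iff all of its required markers were observed; every other
#' group is excluded and reported with a missing required marker --
#' absence is treated as informative, the basis of the exclusion argument
#' for community samples. Positives not explained by any compatible group's
#' required or variable markers are reported separately.
#'
#' @param pattern A [marker_pattern()]; untested markers are allowed and,
#'   with `absence_informative = FALSE`, absent markers do not exclude.
#' @param matrix Decision matrix.
#' @param absence_informative If `FALSE`, only markers explicitly tested
#'   negative count as absent evidence; untested required markers do not
#'   exclude a group. Default `TRUE` (all non-present markers exclude).
#' @return A list of class `deconvolution`: `compatible_groups`,
#'   `excluded_groups` (data frame group/missing_marker),
#'   `unexplained_positives`.
#' @examples
#' panel <- builtin_panel()
#' deconvolve_pattern(
#'   marker_pattern("soil", present = c("DGPf_0", "DGPf_3", "DGPf_5", "DGPf_7")),
#'   panel$matrix
#' )
#' @export
deconvolve_pattern <- function(pattern, matrix, absence_informative = TRUE) {
  check_pattern_panel(pattern, matrix)
  present <- pattern$present
  groups <- colnames(matrix)
  tested_neg <- pattern$absent
  compat <- logical(length(groups))
  missing_marker <- character(length(groups))
  for (i in seq_along(groups)) {
    req <- required_markers(matrix, groups[i])
    miss <- setdiff(req, present)
    if (!absence_informative) miss <- intersect(miss, tested_neg)
    compat[i] <- length(miss) == 0
    missing_marker[i] <- if (compat[i]) NA_character_ else miss[1]
  }
  explained <- unique(unlist(lapply(groups[compat], function(g) {
    c(required_markers(matrix, g), variable_markers(matrix, g))
  })))
  structure(list(
    sample_id = pattern$sample_id,
    compatible_groups = groups[compat],
    excluded_groups = data.frame(group = groups[!compat],
                                 missing_marker = missing_marker[!compat],
                                 stringsAsFactors = FALSE),
    unexplained_positives = setdiff(present, explained)
  ), class = "deconvolution")
}

#' @export
print.deconvolution <- function(x, ...) {
  cat(sprintf("%s: compatible with {%s}\n", x$sample_id,
              paste(x$compatible_groups, collapse = ", ")))
  if (length(x$unexplained_positives)) {
    cat("  unexplained positives:",
        paste(x$unexplained_positives, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Enumerate all full patterns of a panel
#'
#' Brute-forces every presence/absence vector over the panel's markers
#' (2^9 = 512 for the built-in panel) and records which group, if any, each
#' strictly matches. Any pattern matching two or more groups is a matrix
#' ambiguity and is flagged; the built-in matrix has none.
#'
#' @param matrix Decision matrix.
#' @param min_positive Minimum positive reactions for an assignment.
#' @return Data frame with one row per pattern: `pattern` (marker ids of the
#'   positives, comma-separated), `n_present`, `assigned_group`,
#'   `n_matching`. The subset with `n_matching >= 2` is attached as
#'   attribute `"ambiguous"`.
#' @export
enumerate_assignments <- function(matrix, min_positive = 2) {
  ids <- rownames(matrix)
  n <- length(ids)
  if (n > 20) stop("enumeration over 2^", n, " patterns refused", call. = FALSE)
  groups <- colnames(matrix)
  req <- lapply(groups, required_markers, matrix = matrix)
  forb <- lapply(groups, forbidden_markers, matrix = matrix)
  res <- vector("list", 2^n)
  for (code in 0:(2^n - 1)) {
    present <- ids[bitwAnd(code, bitwShiftL(1L, seq_len(n) - 1L)) > 0L]
    ok <- vapply(seq_along(groups), function(i) {
      all(req[[i]] %in% present) && !any(forb[[i]] %in% present)
    }, logical(1))
    n_match <- sum(ok)
    assigned <- if (n_match == 1 && length(present) >= min_positive) {
      groups[ok]
    } else "none"
    res[[code + 1]] <- data.frame(
      pattern = paste(present, collapse = ","),
      n_present = length(present),
      assigned_group = assigned,
      n_matching = n_match,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  amb <- out[out$n_matching >= 2, , drop = FALSE]
  if (nrow(amb)) {
    warning("decision matrix is ambiguous for ", nrow(amb), " pattern(s)",
            call. = FALSE)
  }
  attr(out, "ambiguous") <- amb
  out
}

# Full patterns that strictly match >= 2 groups, with the group lists.
ambiguous_patterns <- function(matrix) {
  tab <- suppressWarnings(enumerate_assignments(matrix, min_positive = 0))
  amb <- attr(tab, "ambiguous")
  if (!nrow(amb)) {
    return(data.frame(pattern = character(0), groups = character(0),
                      stringsAsFactors = FALSE))
  }
  groups <- colnames(matrix)
  amb$groups <- vapply(strsplit(amb$pattern, ","), function(present) {
    ok <- vapply(groups, function(g) {
      all(required_markers(matrix, g) %in% present) &&
        !any(forbidden_markers(matrix, g) %in% present)
    }, logical(1))
    paste(groups[ok], collapse = ", ")
  }, character(1))
  amb[, c("pattern", "groups")]
}

#' Canonical signature of each group
#'
#' The full pattern with exactly the group's required markers present and
#' everything else (forbidden and variable alike) absent.
#'
#' @param matrix Decision matrix.
#' @return Named list: group -> character vector of present marker ids.
#' @export
canonical_signatures <- function(matrix) {
  setNames(lapply(colnames(matrix), required_markers, matrix = matrix),
           colnames(matrix))
}

#' Accuracy accounting for a validation campaign
#'
#' Summarizes a test of the panel against `n_tested` genomes of which
#' `n_identified` produced a positive identification pattern,
#' `n_concordant` of those agreed with an independent (phylogenomic)
#' assignment, and `n_false_negative` genomes that should have been
#' identified were missed. Misidentified = false positives
#' (`n_identified - n_concordant`) + false negatives; accuracy = proportion
#' of tested genomes not misidentified. Percentages use half-up rounding at
#' the conventional precisions (2 decimals for accuracy, 1 elsewhere).
#'
#' @param n_tested,n_identified,n_concordant,n_false_negative Non-negative
#'   integer counts with `n_concordant <= n_identified <= n_tested`.
#' @return A list of class `accuracy_summary` with the integer fields plus
#'   `n_false_positive`, `pct_accuracy`, `pct_concordant`,
#'   `pct_false_positive`.
#' @examples
#' accuracy_summary(421, 225, 218, 0)  # 98.34% accuracy
#' @export
accuracy_summary <- function(n_tested, n_identified, n_concordant,
                             n_false_negative = 0) {
  n <- c(n_tested, n_identified, n_concordant, n_false_negative)
  if (any(n < 0) || any(n != round(n))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (!(n_concordant <= n_identified && n_identified <= n_tested)) {
    stop("need n_concordant <= n_identified <= n_tested", call. = FALSE)
  }
  n_fp <- n_identified - n_concordant
  n_mis <- n_fp + n_false_negative
  structure(list(
    n_tested = n_tested, n_identified = n_identified,
    n_concordant = n_concordant, n_false_positive = n_fp,
    n_false_negative = n_false_negative,
    pct_accuracy = round_half_up(100 * (n_tested - n_mis) / n_tested, 2),
    pct_concordant = if (n_identified > 0) {
      round_half_up(100 * n_concordant / n_identified, 1)
    } else NA_real_,
    pct_false_positive = if (n_identified > 0) {
      round_half_up(100 * n_fp / n_identified, 1)
    } else NA_real_
  ), class = "accuracy_summary")
}

#' @export
print.accuracy_summary <- function(x, ...) {
  cat(sprintf(
    "%d genomes tested; %d identified, %d concordant (%.1f%%), %d false positive (%.1f%%), %d false negative\noverall accuracy %.2f%%\n",
    x$n_tested, x$n_identified, x$n_concordant, x$pct_concordant,
    x$n_false_positive, x$pct_false_positive, x$n_false_negative,
    x$pct_accuracy))
  invisible(x)
}
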