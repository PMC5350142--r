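# Format round-tripping: panel TSV/JSON, pattern TSV, amplicon TSV and BED6
# exports, classification and deconvolution reports. All tables are
# tab-separated with '#' comment lines and a mandatory header; coordinates
# are 1-based inclusive everywhere except the BED export (0-based
# half-open), and each writer states its convention in a header comment.

POSITIVE_TOKENS <- c("+", "1", "POS", "TRUE")
NEGATIVE_TOKENS <- c("-", "0", "NEG", "FALSE", "\u2212")
UNTESTED_TOKENS <- c("", "NA", ".", "?")

read_tsv_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)                 # CRLF tolerated
  lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
}

parse_tsv <- function(path) {
  lines <- read_tsv_lines(path)
  if (!length(lines)) stop("no header row in ", path, call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  # strsplit drops trailing empty fields; restore them from the tab count
  nf <- nchar(lines) - nchar(gsub("\t", "", lines, fixed = TRUE)) + 1L
  cells <- lapply(seq_along(cells), function(i) {
    c(cells[[i]], rep("", nf[i] - length(cells[[i]])))
  })
  header <- trimws(cells[[1]])
  rows <- cells[-1]
  bad <- which(lengths(rows) != length(header))
  if (length(bad)) {
    stop("malformed row ", bad[1] + 1L, " in ", path, ": expected ",
         length(header), " fields, found ", lengths(rows)[bad[1]],
         call. = FALSE)
  }
  df <- as.data.frame(do.call(rbind, lapply(rows, trimws)),
                      stringsAsFactors = FALSE)
  names(df) <- header
  df
}

#' Read a marker pattern table
#'
#' Tab-separated, `#` comments, mandatory header: a `sample_id` column plus
#' one column per marker holding `+`/`-` (also accepted: `1`/`0`,
#' `POS`/`NEG`); an empty cell, `NA`, `.` or `?` marks the marker untested.
#' Columns that are neither `sample_id`, a panel marker, nor whitelisted in
#' `extra_cols` are an error. CRLF line endings parse identically to LF.
#'
#' @param path Pattern TSV path.
#' @param markers Marker table defining the panel (default: built-in).
#' @param extra_cols Non-marker annotation columns to carry through.
#' @return List of [marker_pattern()] objects; any `extra_cols` values are
#'   attached to each pattern as attribute `"annotations"`.
#' @export
read_pattern_table <- function(path, markers = builtin_panel()$markers,
                               extra_cols = character(0)) {
  df <- parse_tsv(path)
  if (!"sample_id" %in% names(df)) {
    stop("pattern table needs a 'sample_id' column", call. = FALSE)
  }
  ids <- markers$marker_id
  marker_cols <- setdiff(names(df), c("sample_id", extra_cols))
  unknown <- setdiff(marker_cols, ids)
  if (length(unknown)) {
    stop("unknown marker column(s) ", paste(unknown, collapse = ", "),
         "; panel markers are ", paste(ids, collapse = ", "), call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    present <- character(0); absent <- character(0)
    for (m in marker_cols) {
      val <- toupper(df[[m]][i])
      if (val %in% POSITIVE_TOKENS) present <- c(present, m)
      else if (val %in% NEGATIVE_TOKENS) absent <- c(absent, m)
      else if (val %in% toupper(UNTESTED_TOKENS)) NULL
      else stop("unrecognized state '", df[[m]][i], "' for marker ", m,
                " in row ", i, " of ", path, call. = FALSE)
    }
    pat <- marker_pattern(df$sample_id[i], present, absent)
    if (length(extra_cols)) {
      attr(pat, "annotations") <-
        setNames(lapply(extra_cols, function(cl) df[[cl]][i]), extra_cols)
    }
    pat
  })
}

#' Write marker patterns to a pattern TSV
#'
#' Inverse of [read_pattern_table()]; byte-stable for fixed input.
#'
#' @param patterns List of [marker_pattern()] objects.
#' @param path Output path.
#' @param markers Marker table defining the column order.
#' @return `path`, invisibly.
#' @export
write_pattern_table <- function(patterns, path,
                                markers = builtin_panel()$markers) {
  ids <- markers$marker_id
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# marker presence/absence patterns (+ / -; empty = untested)",
               paste(c("sample_id", ids), collapse = "\t")), con)
  for (p in patterns) {
    states <- ifelse(ids %in% p$present, "+",
                     ifelse(ids %in% p$absent, "-", ""))
    writeLines(paste(c(p$sample_id, states), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a marker panel to its TSV + JSON serialization
#'
#' The marker table goes to a TSV (one marker per row); the decision matrix
#' to a JSON object `{group: {marker_id: "+"|"-"|plus-minus}}`.
#'
#' @param panel A `marker_panel` (see [builtin_panel()]).
#' @param markers_path,matrix_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_panel <- function(panel, markers_path, matrix_path) {
  m <- panel$markers
  cols <- c("marker_id", "gene_label", "fwd_name", "fwd_seq", "rev_name",
            "rev_seq", "anneal_temp", "target_start", "target_end",
            "expected_len")
  con <- file(markers_path, "w")
  writeLines(c("# marker panel: one diagnostic marker per row",
               paste(cols, collapse = "\t")), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(vapply(cols, function(cl) as.character(m[[cl]][i]),
                            character(1)), collapse = "\t"), con)
  }
  close(con)
  mat <- panel$matrix
  obj <- setNames(lapply(colnames(mat), function(g) as.list(mat[, g])),
                  colnames(mat))
  jsonlite::write_json(obj, matrix_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(markers_path, matrix_path))
}

#' Read a marker panel from its TSV + JSON serialization
#'
#' @param markers_path,matrix_path Paths written by [write_panel()].
#' @return A `marker_panel` list (`markers`, `matrix`).
#' @export
read_panel <- function(markers_path, matrix_path) {
  df <- parse_tsv(markers_path)
  for (cl in c("anneal_temp")) df[[cl]] <- as.numeric(df[[cl]])
  for (cl in c("target_start", "target_end", "expected_len")) {
    df[[cl]] <- as.integer(df[[cl]])
  }
  obj <- jsonlite::read_json(matrix_path)
  groups <- names(obj)
  ids <- df$marker_id
  states <- marker_states()
  norm <- function(x) {
    x <- as.character(x)
    if (x %in% c("+-", "+/-", "v", "V", states[["variable"]])) states[["variable"]]
    else if (x %in% c("+", "1")) "+"
    else if (x %in% c("-", "0", "\u2212")) "-"
    else stop("invalid matrix state '", x, "'", call. = FALSE)
  }
  mat <- matrix(NA_character_, nrow = length(ids), ncol = length(groups),
                dimnames = list(ids, groups))
  for (g in groups) {
    for (m in names(obj[[g]])) {
      if (!m %in% ids) {
        stop("matrix entry for unknown marker '", m, "'", call. = FALSE)
      }
      mat[m, g] <- norm(obj[[g]][[m]])
    }
  }
  structure(list(markers = df, matrix = mat), class = "marker_panel")
}

#' Write an amplicon prediction table as TSV
#'
#' @param amplicons Data frame from [predict_amplicons()] /
#'   [profile_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_amplicon_table <- function(amplicons, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# predicted amplicons; coordinates 1-based inclusive", con)
  cols <- names(empty_amplicons())
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(amplicons)) {
    for (i in seq_len(nrow(amplicons))) {
      writeLines(paste(vapply(cols, function(cl) {
        as.character(amplicons[[cl]][i])
      }, character(1)), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Export predicted amplicons as BED6
#'
#' BED uses 0-based half-open coordinates (`start - 1`, `end`), unlike every
#' other table in this package; `name` is the marker id, `score` the product
#' length, and `strand` `+` for `fwd/rev` orientation, `-` for `rev/fwd`.
#'
#' @inheritParams write_amplicon_table
#' @return `path`, invisibly.
#' @export
write_amplicon_bed <- function(amplicons, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# BED6: 0-based half-open (converted from 1-based ",
                    "inclusive product coordinates)"), con)
  if (nrow(amplicons)) {
    for (i in seq_len(nrow(amplicons))) {
      writeLines(paste(
        amplicons$template_id[i], amplicons$product_start[i] - 1L,
        amplicons$product_end[i], amplicons$marker_id[i],
        amplicons$product_len[i],
        if (amplicons$orientation[i] == "fwd/rev") "+" else "-",
        sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Write classification (or deconvolution) reports
#'
#' Produces `classification.tsv` + `classification.json` for a list of
#' `phylogroup_call` objects, or `deconvolution.tsv` + `deconvolution.json`
#' for `deconvolution` objects.
#'
#' @param results List of results from [classify_pattern()] or
#'   [deconvolve_pattern()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_reports <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!length(results)) stop("no results to write", call. = FALSE)
  if (inherits(results[[1]], "phylogroup_call")) {
    tsv <- file.path(dir, "classification.tsv")
    con <- file(tsv, "w")
    writeLines(c("# phylogroup classification report",
                 "sample_id\tassigned_group\tn_positive\tsupporting_markers\tconflicts"),
               con)
    for (r in results) {
      conf <- if (nrow(r$conflicts)) {
        paste(paste0(r$conflicts$group, ":", r$conflicts$marker), collapse = ";")
      } else ""
      writeLines(paste(r$sample_id, r$assigned_group, r$n_positive,
                       paste(sort(r$supporting_markers), collapse = ","),
                       conf, sep = "\t"), con)
    }
    close(con)
    json <- file.path(dir, "classification.json")
    jsonlite::write_json(lapply(results, function(r) {
      list(sample_id = r$sample_id, assigned_group = r$assigned_group,
           n_positive = r$n_positive,
           supporting_markers = as.list(sort(r$supporting_markers)))
    }), json, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(c(tsv, json)))
  }
  tsv <- file.path(dir, "deconvolution.tsv")
  con <- file(tsv, "w")
  writeLines(c("# phylogroup deconvolution report",
               "sample_id\tcompatible_groups\texcluded_groups\tunexplained_positives"),
             con)
  for (r in results) {
    writeLines(paste(
      r$sample_id,
      paste(r$compatible_groups, collapse = ";"),
      paste(paste0(r$excluded_groups$group, ":",
                   r$excluded_groups$missing_marker), collapse = ";"),
      paste(r$unexplained_positives, collapse = ";"),
      sep = "\t"), con)
  }
  close(con)
  json <- file.path(dir, "deconvolution.json")
  jsonlite::write_json(lapply(results, function(r) {
    list(sample_id = r$sample_id,
         compatible_groups = as.list(r$compatible_groups),
         excluded_groups = r$excluded_groups,
         unexplained_positives = as.list(r$unexplained_positives))
  }), json, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(tsv, json))
}
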