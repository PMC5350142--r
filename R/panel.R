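# The nine-marker diagnostic panel for the P. fluorescens species complex:
# primer pairs, target coordinates on each marker gene, and the marker-by-
# phylogroup decision matrix with required (+), forbidden (-) and variable
# (+/-) states.

STATE_REQUIRED <- "+"
STATE_FORBIDDEN <- "-"
STATE_VARIABLE <- "\u00b1"

#' Phylogroups of the P. fluorescens species complex
#'
#' The eight phylogroups, in panel column order.
#'
#' @return Character vector of length 8.
#' @export
pfl_groups <- function() {
  c("P. corrugata", "P. koreensis", "P. jessenii", "P. mandelii",
    "P. gessardii", "P. fluorescens", "P. protegens", "P. chlororaphis")
}

#' Marker state codes
#'
#' @return Named character vector mapping `required`, `forbidden`, `variable`
#'   to their display symbols (`+`, `-`, plus-minus).
#' @export
marker_states <- function() {
  c(required = STATE_REQUIRED, forbidden = STATE_FORBIDDEN,
    variable = STATE_VARIABLE)
}

builtin_marker_table <- function() {
  markers <- data.frame(
    marker_id = paste0("DGPf_", 0:8),
    gene_label = c(
      "hypothetical protein (PSF113_RS56935)",
      "type I secretion target (PSF113_RS30625)",
      "FAD dependent oxidoreductase (PFL01_RS10805)",
      "glutamine synthetase (PputUW4_01890)",
      "KWG repeat-containing protein (PFL_RS20920)",
      "3-phosphoshikimate 1-carboxyvinyltransferase (PFLA506_RS14455)",
      "LysR family transcriptional regulator (PFL_RS18605)",
      "LysR family transcriptional regulator (PFLU_RS11255)",
      "LuxR family transcriptional regulator (PCL1606_12410)"
    ),
    fwd_name = paste0("DGPf_", 0:8, "F"),
    fwd_seq = c(
      "CATCGCAATCGCACRATGATY",
      "TGCAGGRAGACGGSAARG",
      "GTRGTSTTCATCGGBGGHGG",
      "CCATGGCCGACCACCACGTCATCATCAARC",
      "CGCTGATCCTCTCGTTGTCTGC",
      "CGGCGTGGGTGTCGATCRR",
      "GCSTTGCGHTAYTTCCACGAGG",
      "CYGARATCGAGGGGCTKTGGA",
      "CCCACCGACAGCCAGCAACG"
    ),
    rev_name = paste0("DGPf_", 0:8, "R"),
    rev_seq = c(
      "GAAAGTCTTGACCAGCARVAG",
      "CCRAGGAAGCCCAGGGAN",
      "TGGCARTACCAGACGTTRTCCG",
      "GCAGTTCCCAGTCGGTKATBCGYCGGTCG",
      "ACGCCCTTGTCCACATCG",
      "GAGTTCGCAGAAAACCGTGACCG",
      "GCCAGGCTYTTCTGCACYTCC",
      "GCTGAARTCTGGVAGCAGGGC",
      "CGGTCTTGTCGCTGATGCCG"
    ),
    anneal_temp = c(64, 64, 64, 64, 64, 67, 67, 64, 67),
    target_start = c(139L, 632L, 88L, 671L, 32L, 3L, 28L, 11L, 127L),
    target_end = c(750L, 1316L, 1088L, 1351L, 1103L, 1117L, 707L, 755L, 787L),
    stringsAsFactors = FALSE
  )
  markers$expected_len <- markers$target_end - markers$target_start + 1L
  markers
}

builtin_decision_matrix <- function() {
  g <- pfl_groups()
  ids <- paste0("DGPf_", 0:8)
  # rows: markers DGPf_0..DGPf_8; columns: phylogroups in pfl_groups() order
  rows <- rbind(
    c("+", "+", "v", "+", "-", "-", "v", "-"),  # DGPf_0
    c("+", "-", "-", "-", "-", "-", "-", "-"),  # DGPf_1
    c("-", "+", "+", "-", "-", "-", "+", "+"),  # DGPf_2
    c("-", "-", "+", "+", "-", "-", "-", "-"),  # DGPf_3
    c("-", "-", "-", "-", "-", "-", "+", "-"),  # DGPf_4
    c("-", "-", "-", "-", "+", "+", "-", "-"),  # DGPf_5
    c("-", "-", "-", "-", "+", "-", "v", "-"),  # DGPf_6
    c("-", "-", "-", "-", "-", "+", "-", "-"),  # DGPf_7
    c("-", "-", "-", "-", "-", "-", "-", "+")   # DGPf_8
  )
  rows[rows == "v"] <- STATE_VARIABLE
  dimnames(rows) <- list(ids, g)
  rows
}

#' The built-in nine-marker phylogroup panel
#'
#' Returns the diagnostic panel shipped with the package: nine degenerate
#' primer pairs (DGPf_0 to DGPf_8), each with its target interval on the
#' marker gene and expected amplicon length, together with the 9 x 8
#' decision matrix giving each marker's state (required / forbidden /
#' variable) in each phylogroup. Any isolate of the complex is assignable
#' from the presence/absence pattern of these nine PCR reactions, with at
#' least two positive reactions backing every assignment.
#'
#' @return A list of class `marker_panel` with elements `markers` (data
#'   frame, one row per marker) and `matrix` (character matrix, markers x
#'   groups, entries `+`, `-` or plus-minus).
#' @examples
#' panel <- builtin_panel()
#' panel$markers[panel$markers$marker_id == "DGPf_1", c("target_start", "target_end", "expected_len")]
#' panel$matrix["DGPf_8", ]
#' @export
builtin_panel <- function() {
  structure(list(markers = builtin_marker_table(),
                 matrix = builtin_decision_matrix()),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("marker panel:", nrow(x$markers), "markers x",
      ncol(x$matrix), "groups\n")
  print(x$markers[, c("marker_id", "fwd_seq", "rev_seq",
                      "target_start", "target_end", "expected_len")],
        row.names = FALSE)
  invisible(x)
}

matrix_states_of <- function(matrix, group, state) {
  rownames(matrix)[matrix[, group] == state]
}

required_markers <- function(matrix, group) {
  matrix_states_of(matrix, group, STATE_REQUIRED)
}
forbidden_markers <- function(matrix, group) {
  matrix_states_of(matrix, group, STATE_FORBIDDEN)
}
variable_markers <- function(matrix, group) {
  matrix_states_of(matrix, group, STATE_VARIABLE)
}

#' Validate a marker panel
#'
#' Checks the structural invariants of a panel: valid IUPAC primer
#' sequences, coherent target coordinates (`expected_len == end - start + 1`),
#' unique marker ids, a complete decision matrix over the declared states,
#' at least two required markers per group (the two-positive-reaction rule),
#' and -- for panels of up to 16 markers -- that no full presence/absence
#' pattern matches two groups (checked by exhaustive enumeration).
#'
#' @param markers Marker data frame as in [builtin_panel()].
#' @param matrix Decision matrix as in [builtin_panel()].
#' @return Character vector of violation descriptions; empty if the panel is
#'   valid. Violations are data, not errors.
#' @export
validate_panel <- function(markers, matrix) {
  v <- character(0)
  need <- c("marker_id", "fwd_seq", "rev_seq", "target_start", "target_end",
            "expected_len")
  miss <- setdiff(need, names(markers))
  if (length(miss)) {
    return(paste("marker table lacks column(s):", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(markers$marker_id)) {
    v <- c(v, paste("duplicate marker_id:",
                    paste(unique(markers$marker_id[duplicated(markers$marker_id)]),
                          collapse = ", ")))
  }
  for (i in seq_len(nrow(markers))) {
    id <- markers$marker_id[i]
    for (side in c("fwd_seq", "rev_seq")) {
      ok <- tryCatch({ iupac_masks(markers[[side]][i]); TRUE },
                     error = function(e) conditionMessage(e))
      if (!isTRUE(ok)) v <- c(v, paste0(id, " ", side, ": ", ok))
    }
    if (markers$target_start[i] >= markers$target_end[i]) {
      v <- c(v, paste0(id, ": target_start must be < target_end"))
    } else if (markers$expected_len[i] !=
               markers$target_end[i] - markers$target_start[i] + 1L) {
      v <- c(v, paste0(id, ": expected_len disagrees with target coordinates"))
    }
  }
  states <- unname(marker_states())
  ids <- markers$marker_id
  if (!setequal(rownames(matrix), ids) ||
      nrow(matrix) != length(ids) || ncol(matrix) < 1) {
    v <- c(v, "incomplete matrix: rows do not cover the marker panel exactly")
    return(v)
  }
  bad_cells <- which(!(matrix %in% states) | is.na(matrix))
  if (length(bad_cells)) {
    rc <- arrayInd(bad_cells[1], dim(matrix))
    v <- c(v, paste0("incomplete matrix: invalid state at (",
                     rownames(matrix)[rc[1]], ", ", colnames(matrix)[rc[2]],
                     ")"))
    return(v)
  }
  for (g in colnames(matrix)) {
    if (length(required_markers(matrix, g)) < 2) {
      v <- c(v, paste0(g, ": fewer than two positive reactions guaranteed ",
                      "(needs >= 2 required markers)"))
    }
  }
  if (length(ids) <= 16) {
    amb <- ambiguous_patterns(matrix)
    if (nrow(amb)) {
      v <- c(v, paste0("ambiguous matrix: pattern {",
                       amb$pattern[1], "} matches groups ",
                       amb$groups[1]))
    }
  }
  v
}
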