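# In-silico PCR: locate degenerate-primer binding sites on template
# sequences under a total and 3'-window mismatch budget, pair sites into
# predicted amplicons, and profile whole genomes against a marker panel.
#
# The search is an exact sliding-window scan over 4-bit IUPAC masks (a
# primer position matches a template position iff the base sets intersect),
# vectorised over all template offsets; no heuristic seeding and no index.
# Desk-scale genomes (<= 10 Mb) complete in seconds.

#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet
NULL

#' In-silico PCR stringency settings
#'
#' Defaults are documented conventions of this package: up to `max_mm`
#' mismatches per primer, none of them (`max_mm_3p = 0`) in the 3'-terminal
#' `window_3p` bases -- the review criterion of weighting mismatches
#' "specially in 3'" made operational -- and a predicted product accepted
#' between `min_len` and `max_len` bp, flagged as matching the marker's
#' expectation within `len_tol` (fraction of the expected length).
#'
#' @param max_mm Maximum total mismatches per primer footprint.
#' @param max_mm_3p Maximum mismatches within the 3' window.
#' @param window_3p Width (nt) of the 3'-terminal window.
#' @param min_len,max_len Product length bounds (bp).
#' @param len_tol Relative tolerance on the expected amplicon length.
#' @param n_strict If `TRUE`, an N in the template counts as a mismatch
#'   against anything (guards against long N runs in draft assemblies).
#' @return A list of class `ispcr_settings`.
#' @export
ispcr_settings <- function(max_mm = 3L, max_mm_3p = 0L, window_3p = 5L,
                           min_len = 50L, max_len = 5000L, len_tol = 0.2,
                           n_strict = FALSE) {
  stopifnot(max_mm >= 0, max_mm_3p >= 0, window_3p >= 0,
            min_len >= 1, max_len >= min_len, len_tol >= 0)
  structure(list(max_mm = as.integer(max_mm),
                 max_mm_3p = as.integer(max_mm_3p),
                 window_3p = as.integer(window_3p),
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 len_tol = len_tol, n_strict = isTRUE(n_strict)),
            class = "ispcr_settings")
}

as_dna_character <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    return(setNames(as.character(x), names(x)))
  }
  if (inherits(x, "DNAString")) return(c(seq1 = as.character(x)))
  if (is.character(x) && length(x) == 1 && !is.null(x) && file.exists(x)) {
    set <- readDNAStringSet(x)
    return(setNames(as.character(set), names(set)))
  }
  if (is.character(x)) {
    nm <- names(x) %||% paste0("seq", seq_along(x))
    return(setNames(unname(x), nm))
  }
  stop("cannot interpret template input (give a DNAStringSet, a named ",
       "character vector, or a FASTA path)", call. = FALSE)
}

empty_sites <- function() {
  data.frame(template_id = character(0), strand = character(0),
             start = integer(0), end = integer(0),
             mismatches_total = integer(0), mismatches_3prime = integer(0),
             primer_name = character(0), stringsAsFactors = FALSE)
}

# Vectorised exact scan of one primer-mask vector over one template-mask
# vector: mismatch totals for every offset, plus the 3'-window subtotal.
scan_masks <- function(pm, tmask, n_strict, max_mm, window_idx) {
  m <- length(pm)
  ns <- length(tmask) - m + 1L
  if (ns < 1L) return(NULL)
  mm_tot <- integer(ns)
  mm_3p <- integer(ns)
  for (j in seq_len(m)) {
    tw <- tmask[j:(j + ns - 1L)]
    bad <- bitwAnd(pm[j], tw) == 0L
    if (n_strict) bad <- bad | tw == 15L
    mm_tot <- mm_tot + bad
    if (j %in% window_idx) mm_3p <- mm_3p + bad
  }
  keep <- which(mm_tot <= max_mm)
  if (!length(keep)) return(NULL)
  list(start = keep, mm_total = mm_tot[keep], mm_3p = mm_3p[keep])
}

# Both-strand site search on a precomputed template mask vector.
sites_on_masks <- function(primer, tmask, tid, settings, primer_name) {
  pm <- iupac_masks(primer)
  plen <- length(pm)
  w <- min(settings$window_3p, plen)
  rows <- list()
  # forward strand: primer 3' end at the right edge of the footprint
  fwd <- scan_masks(pm, tmask, settings$n_strict, settings$max_mm,
                    if (w > 0) (plen - w + 1L):plen else integer(0))
  if (!is.null(fwd)) {
    rows[[1]] <- data.frame(
      template_id = tid, strand = "+", start = fwd$start,
      end = fwd$start + plen - 1L, mismatches_total = fwd$mm_total,
      mismatches_3prime = fwd$mm_3p, primer_name = primer_name,
      stringsAsFactors = FALSE)
  }
  # reverse strand: scan the reverse complement; the primer 3' end then
  # sits at the left edge of the footprint
  rpm <- rev(COMP_MASK[pm])
  rev_hits <- scan_masks(rpm, tmask, settings$n_strict, settings$max_mm,
                         if (w > 0) seq_len(w) else integer(0))
  if (!is.null(rev_hits)) {
    rows[[2]] <- data.frame(
      template_id = tid, strand = "-", start = rev_hits$start,
      end = rev_hits$start + plen - 1L, mismatches_total = rev_hits$mm_total,
      mismatches_3prime = rev_hits$mm_3p, primer_name = primer_name,
      stringsAsFactors = FALSE)
  }
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty_sites())
  res <- do.call(rbind, rows)
  res[res$mismatches_3prime <= settings$max_mm_3p, , drop = FALSE]
}

#' Find primer binding sites on a template
#'
#' Reports every footprint, on both strands, where the primer matches the
#' template with at most `max_mm` total mismatches and at most `max_mm_3p`
#' mismatches inside the 3'-terminal `window_3p` bases. A primer position
#' matches a template position iff their IUPAC base sets intersect (see
#' [iupac_match()]); in N-strict mode a template N is always a mismatch.
#' On the forward strand the 3' window sits at the right edge of the
#' footprint; on the reverse strand, at the left edge.
#'
#' @param primer IUPAC primer string (5' to 3').
#' @param template `DNAStringSet`, named character vector, or FASTA path.
#' @param settings An [ispcr_settings()] object.
#' @param primer_name Label carried into the output.
#' @return Data frame of binding sites sorted by (template_id, start):
#'   `template_id`, `strand` (`+`/`-`), `start`, `end` (1-based inclusive),
#'   `mismatches_total`, `mismatches_3prime`, `primer_name`.
#' @export
find_binding_sites <- function(primer, template, settings = ispcr_settings(),
                               primer_name = "primer") {
  stopifnot(inherits(settings, "ispcr_settings"))
  primer <- toupper(primer)
  if (nchar(primer) < settings$window_3p) {
    stop("primer shorter than the 3' window", call. = FALSE)
  }
  templates <- as_dna_character(template)
  out <- lapply(seq_along(templates), function(i) {
    if (nchar(templates[i]) < nchar(primer)) return(NULL)
    sites_on_masks(primer, iupac_masks(templates[i]), names(templates)[i],
                   settings, primer_name)
  })
  out <- Filter(function(x) !is.null(x) && nrow(x) > 0, out)
  if (!length(out)) return(empty_sites())
  res <- do.call(rbind, out)
  res <- res[order(res$template_id, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_amplicons <- function() {
  data.frame(template_id = character(0), marker_id = character(0),
             orientation = character(0),
             product_start = integer(0), product_end = integer(0),
             product_len = integer(0),
             fwd_start = integer(0), fwd_end = integer(0), fwd_mm = integer(0),
             rev_start = integer(0), rev_end = integer(0), rev_mm = integer(0),
             within_expected = logical(0), stringsAsFactors = FALSE)
}

pair_sites <- function(plus, minus, orientation, tid, marker_id, expected_len,
                       settings) {
  if (is.null(plus) || is.null(minus) || !nrow(plus) || !nrow(minus)) {
    return(NULL)
  }
  rows <- list()
  for (i in seq_len(nrow(plus))) {
    for (j in seq_len(nrow(minus))) {
      if (plus$start[i] > minus$start[j] || plus$end[i] > minus$end[j]) next
      len <- minus$end[j] - plus$start[i] + 1L
      if (len < settings$min_len || len > settings$max_len) next
      within <- if (is.na(expected_len)) NA else {
        abs(len - expected_len) <= settings$len_tol * expected_len
      }
      rows[[length(rows) + 1L]] <- data.frame(
        template_id = tid, marker_id = marker_id, orientation = orientation,
        product_start = plus$start[i], product_end = minus$end[j],
        product_len = len,
        fwd_start = plus$start[i], fwd_end = plus$end[i],
        fwd_mm = plus$mismatches_total[i],
        rev_start = minus$start[j], rev_end = minus$end[j],
        rev_mm = minus$mismatches_total[j],
        within_expected = within, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

# Amplicon prediction on one template's precomputed mask vector.
amplicons_on_masks <- function(marker, tmask, tid, settings) {
  marker_id <- marker$marker_id %||% "pair"
  expected_len <- marker$expected_len %||% NA_integer_
  sf <- sites_on_masks(toupper(marker$fwd_seq), tmask, tid, settings, "fwd")
  sr <- sites_on_masks(toupper(marker$rev_seq), tmask, tid, settings, "rev")
  out <- list(
    pair_sites(sf[sf$strand == "+", , drop = FALSE],
               sr[sr$strand == "-", , drop = FALSE],
               "fwd/rev", tid, marker_id, expected_len, settings),
    pair_sites(sr[sr$strand == "+", , drop = FALSE],
               sf[sf$strand == "-", , drop = FALSE],
               "rev/fwd", tid, marker_id, expected_len, settings))
  out <- Filter(Negate(is.null), out)
  if (length(out)) do.call(rbind, out) else NULL
}

#' Predict PCR amplicons of a primer pair on templates
#'
#' Pairs forward-strand sites of one primer with reverse-strand sites of the
#' other (in both role assignments, so predictions are invariant under
#' reverse-complementing the template) and reports every correctly oriented
#' combination whose product length falls within the settings' bounds. The
#' product spans from the first base of the upstream footprint to the last
#' base of the downstream footprint, 1-based inclusive -- under which the
#' panel's printed target coordinates reproduce the printed amplicon
#' lengths exactly.
#'
#' @param marker A one-row data frame (or list) with `fwd_seq`, `rev_seq`,
#'   and optionally `marker_id` and `expected_len` (used for the
#'   `within_expected` flag).
#' @param template `DNAStringSet`, named character vector, or FASTA path.
#' @param settings An [ispcr_settings()] object.
#' @return Data frame of predictions, one row per amplicon, in deterministic
#'   (template, product_start, product_end) order: product coordinates and
#'   length, both footprints with mismatch totals, `orientation`
#'   (`"fwd/rev"` or `"rev/fwd"`), and `within_expected`.
#' @export
predict_amplicons <- function(marker, template, settings = ispcr_settings()) {
  marker <- as.list(marker)
  templates <- as_dna_character(template)
  out <- lapply(seq_along(templates), function(i) {
    amplicons_on_masks(marker, iupac_masks(templates[i]),
                       names(templates)[i], settings)
  })
  out <- Filter(Negate(is.null), out)
  if (!length(out)) return(empty_amplicons())
  res <- do.call(rbind, out)
  res <- res[order(res$template_id, res$product_start, res$product_end,
                   res$orientation), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Profile a genome against a marker panel
#'
#' Runs [predict_amplicons()] for every marker of the panel over all contigs
#' and calls a marker present iff at least one predicted amplicon matches
#' the expected length within tolerance (`within_expected`). The amplicon
#' evidence is retained for reporting. Each contig is converted to its
#' IUPAC mask vector once and shared across all markers.
#'
#' @param markers Marker data frame as in [builtin_panel()].
#' @param genome `DNAStringSet`, named character vector, or FASTA path
#'   (multi-record; gzip accepted).
#' @param settings An [ispcr_settings()] object.
#' @param sample_id Label for the resulting pattern (defaults to the FASTA
#'   file name, or `"genome"`).
#' @return A [marker_pattern()] with attribute `"amplicons"` (the evidence
#'   table) -- ready for [classify_pattern()] or [deconvolve_pattern()].
#' @export
profile_genome <- function(markers, genome, settings = ispcr_settings(),
                           sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- if (is.character(genome) && length(genome) == 1 &&
                     file.exists(genome)) {
      sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(genome))
    } else "genome"
  }
  templates <- as_dna_character(genome)
  masks <- lapply(templates, iupac_masks)
  evid <- list()
  present <- character(0)
  for (i in seq_len(nrow(markers))) {
    marker <- as.list(markers[i, ])
    amps <- list()
    for (k in seq_along(masks)) {
      amps[[k]] <- amplicons_on_masks(marker, masks[[k]],
                                      names(templates)[k], settings)
    }
    amps <- Filter(Negate(is.null), amps)
    amps <- if (length(amps)) do.call(rbind, amps) else empty_amplicons()
    if (nrow(amps) && any(amps$within_expected %in% TRUE)) {
      present <- c(present, markers$marker_id[i])
    }
    evid[[i]] <- amps
  }
  pat <- marker_pattern(sample_id, present = present,
                        absent = setdiff(markers$marker_id, present))
  attr(pat, "amplicons") <- do.call(rbind, evid)
  pat
}
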