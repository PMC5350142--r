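# Shared fixtures and independent oracles used across the suite.

PANEL <- builtin_panel()
MARKER_IDS <- PANEL$markers$marker_id
GROUPS <- pfl_groups()

full_pattern <- function(present, sample_id = "s") {
  marker_pattern(sample_id, present = present,
                 absent = setdiff(MARKER_IDS, present))
}

iupac_alphabet <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                    "B", "D", "H", "V", "N")

random_iupac <- function(n, degenerate_frac = 0.2) {
  paste(ifelse(runif(n) < degenerate_frac,
               sample(iupac_alphabet[5:15], n, replace = TRUE),
               sample(iupac_alphabet[1:4], n, replace = TRUE)),
        collapse = "")
}

random_acgt <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Independent naive O(n*m) site scan: per-position character loop built on
# iupac_match(), completely separate from the package's mask engine.
naive_sites <- function(primer, template, settings) {
  pchars <- strsplit(primer, "")[[1]]
  out <- list()
  scan <- function(seq, strand, window_idx_of) {
    tchars <- strsplit(seq, "")[[1]]
    m <- length(pchars)
    if (length(tchars) < m) return()
    for (s in seq_len(length(tchars) - m + 1)) {
      mm <- !mapply(iupac_match, pchars, tchars[s:(s + m - 1)])
      if (settings$n_strict) mm <- mm | tchars[s:(s + m - 1)] == "N"
      w <- min(settings$window_3p, m)
      mm3 <- if (w > 0) sum(mm[window_idx_of(m, w)]) else 0
      if (sum(mm) <= settings$max_mm && mm3 <= settings$max_mm_3p) {
        out[[length(out) + 1]] <<- data.frame(
          strand = strand, start = s, end = s + m - 1,
          mismatches_total = sum(mm), mismatches_3prime = mm3,
          stringsAsFactors = FALSE)
      }
    }
  }
  scan(template, "+", function(m, w) (m - w + 1):m)
  # reverse strand: compare revcomp(primer) left-to-right; 3' window at left
  pchars <- strsplit(revcomp_chr(primer), "")[[1]]
  scan(template, "-", function(m, w) 1:w)
  if (!length(out)) {
    return(data.frame(strand = character(0), start = integer(0),
                      end = integer(0), mismatches_total = integer(0),
                      mismatches_3prime = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$strand), , drop = FALSE]
}
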