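# Group-specific marker discovery from a pan-genome orthology table, the
# desk-scale similarity re-screen, and the conserved-block degenerate primer
# designer. Orthology inference itself (all-vs-all clustering) is out of
# scope: this module consumes a precomputed table.

#' Construct an orthology table
#'
#' @param genomes Data frame with columns `genome_id`, `group`.
#' @param membership Long-format data frame with columns `genome_id`,
#'   `orthogroup`, `cds_id`.
#' @param sequences Named character vector (or `DNAStringSet`) of CDS
#'   nucleotide sequences, names matching `membership$cds_id`.
#' @return A list of class `ortho_table`.
#' @export
ortho_table <- function(genomes, membership, sequences) {
  stopifnot(all(c("genome_id", "group") %in% names(genomes)),
            all(c("genome_id", "orthogroup", "cds_id") %in% names(membership)))
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  missing <- setdiff(membership$cds_id, names(sequences))
  if (length(missing)) {
    stop("membership references CDS id(s) without a sequence: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(membership$genome_id, genomes$genome_id)
  if (length(unknown)) {
    stop("membership references unknown genome(s): ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(genomes = genomes, membership = membership,
                 sequences = sequences),
            class = "ortho_table")
}

#' @export
print.ortho_table <- function(x, ...) {
  cat(sprintf("ortho_table: %d genomes in %d groups, %d orthogroups, %d CDS\n",
              nrow(x$genomes), length(unique(x$genomes$group)),
              length(unique(x$membership$orthogroup)), length(x$sequences)))
  invisible(x)
}

align_pid <- function(a, b) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(DNAString(a), DNAString(b),
                                       type = "local",
                                       substitutionMatrix = sm,
                                       gapOpening = 2, gapExtension = 1)
  alen <- Biostrings::nchar(aln)
  list(identity = if (alen > 0) Biostrings::pid(aln) / 100 else 0,
       coverage_query = if (alen > 0) {
         nchar(gsub("-", "", as.character(Biostrings::alignedPattern(aln)))) /
           nchar(a)
       } else 0,
       score = Biostrings::score(aln))
}

#' Screen a query sequence against a set of subjects
#'
#' Local alignment (match +1, mismatch -1, gap open 2, gap extend 1) of the
#' query -- and, with `both_strands`, its reverse complement -- against each
#' subject. A hit is declared when query coverage and identity both reach
#' their thresholds. This identity+coverage criterion stands in for a
#' database-size-dependent e-value cut-off.
#'
#' @param query Nucleotide sequence (character).
#' @param subjects Named character vector of subject sequences.
#' @param min_cov Minimum fraction of the query covered by the alignment.
#' @param min_id Minimum alignment identity (fraction).
#' @param both_strands Also screen the reverse complement. Default `TRUE`.
#' @return Data frame, one row per subject: `subject_id`, `identity`,
#'   `coverage`, `strand`, `hit`; sorted by decreasing identity.
#' @export
similarity_screen <- function(query, subjects, min_cov = 0.5, min_id = 0.7,
                              both_strands = TRUE) {
  stopifnot(is.character(query), nzchar(query))
  if (!length(subjects)) {
    return(data.frame(subject_id = character(0), identity = numeric(0),
                      coverage = numeric(0), strand = character(0),
                      hit = logical(0), stringsAsFactors = FALSE))
  }
  nm <- names(subjects) %||% paste0("subject", seq_along(subjects))
  rc <- if (both_strands) reverse_complement(query) else NULL
  rows <- lapply(seq_along(subjects), function(i) {
    best <- align_pid(query, subjects[[i]])
    strand <- "+"
    if (both_strands) {
      alt <- align_pid(rc, subjects[[i]])
      if (alt$score > best$score) { best <- alt; strand <- "-" }
    }
    data.frame(subject_id = nm[i], identity = best$identity,
               coverage = best$coverage_query, strand = strand,
               hit = best$coverage_query >= min_cov &&
                 best$identity >= min_id,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res[order(-res$identity, res$subject_id), , drop = FALSE]
}

mean_pairwise_identity <- function(seqs) {
  if (length(seqs) < 2) return(1)
  pairs <- utils::combn(length(seqs), 2)
  mean(apply(pairs, 2, function(p) {
    align_pid(seqs[[p[1]]], seqs[[p[2]]])$identity
  }))
}

#' Find group-specific candidate markers in a pan-genome
#'
#' Re-implements the comparative-genomics filter behind the panel: a
#' candidate orthogroup must (i) have a member in every genome of the target
#' group and in no genome outside it, (ii) have a representative CDS of at
#' least `min_len` bp, (iii) be highly conserved within the group (mean
#' pairwise identity >= `id_within`), and (iv) survive a sequence-level
#' re-screen -- no local-alignment hit at `max_cross` identity and 50%
#' coverage against any out-group CDS, so near-identical unclustered copies
#' still disqualify a candidate.
#'
#' @param ortho An [ortho_table()].
#' @param group Target group label.
#' @param min_len Minimum representative CDS length (bp). Default 500.
#' @param id_within Minimum mean pairwise within-group identity. Default 0.8.
#' @param max_cross Identity threshold above which an out-group alignment
#'   (at >= `min_cov` coverage) disqualifies. Default 0.7.
#' @param min_cov Coverage threshold for the re-screen. Default 0.5.
#' @return Data frame of all group-core/absent-elsewhere orthogroups with
#'   columns `orthogroup`, `target_group`, `representative`, `length`,
#'   `min_len_ok`, `core_in_group`, `absent_outside`,
#'   `within_group_identity`, `cross_group_best_hit`, `accepted`; accepted
#'   candidates first, by decreasing within-group identity.
#' @export
find_group_specific <- function(ortho, group, min_len = 500L,
                                id_within = 0.8, max_cross = 0.7,
                                min_cov = 0.5) {
  stopifnot(inherits(ortho, "ortho_table"))
  if (!nrow(ortho$membership)) stop("empty ortho_table", call. = FALSE)
  if (!group %in% ortho$genomes$group) {
    stop("unknown group '", group, "'; groups are: ",
         paste(unique(ortho$genomes$group), collapse = ", "), call. = FALSE)
  }
  in_group <- ortho$genomes$genome_id[ortho$genomes$group == group]
  out_group <- setdiff(ortho$genomes$genome_id, in_group)
  mem <- ortho$membership
  ogs <- unique(mem$orthogroup)
  # out-group CDS pool for the similarity re-screen
  out_cds <- mem$cds_id[mem$genome_id %in% out_group]
  out_seqs <- ortho$sequences[out_cds]
  rows <- list()
  for (og in ogs) {
    sub <- mem[mem$orthogroup == og, , drop = FALSE]
    carriers <- unique(sub$genome_id)
    core <- all(in_group %in% carriers)
    absent <- !any(carriers %in% out_group)
    if (!core || !absent) next
    member_seqs <- ortho$sequences[sub$cds_id]
    rep_i <- which.max(nchar(member_seqs))
    rep_id <- sub$cds_id[rep_i]
    rep_seq <- member_seqs[[rep_i]]
    wgi <- mean_pairwise_identity(member_seqs)
    screen <- similarity_screen(rep_seq, out_seqs, min_cov = min_cov,
                                min_id = max_cross)
    best_cross <- if (nrow(screen)) {
      max(screen$identity[screen$coverage >= min_cov], 0)
    } else 0
    any_hit <- nrow(screen) > 0 && any(screen$hit)
    len_ok <- nchar(rep_seq) >= min_len
    rows[[length(rows) + 1L]] <- data.frame(
      orthogroup = og, target_group = group, representative = rep_id,
      length = nchar(rep_seq), min_len_ok = len_ok,
      core_in_group = core, absent_outside = absent,
      within_group_identity = wgi, cross_group_best_hit = best_cross,
      accepted = len_ok && wgi >= id_within && !any_hit,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(orthogroup = character(0), target_group = character(0),
                      representative = character(0), length = integer(0),
                      min_len_ok = logical(0), core_in_group = logical(0),
                      absent_outside = logical(0),
                      within_group_identity = numeric(0),
                      cross_group_best_hit = numeric(0),
                      accepted = logical(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res[order(-res$accepted, -res$within_group_identity, res$orthogroup), ,
      drop = FALSE]
}

# Per-column consensus over a gapless alignment block; NULL if any gap.
column_consensus <- function(aln_chars, cols) {
  vapply(cols, function(j) {
    bases <- unique(aln_chars[, j])
    if (any(bases == "-")) return(NA_character_)
    consensus_code(bases)
  }, character(1))
}

#' Design a degenerate primer pair on aligned orthologs
#'
#' Scans a gap-aware multiple alignment of a marker's orthologs for
#' conserved windows: runs of gap-free columns whose per-column consensus
#' (minimal IUPAC code over the observed bases) keeps the whole-window
#' degeneracy within budget and whose Tm range intersects `tm_window`.
#' Windows are ranked lexicographically (lower degeneracy, then Tm-range
#' midpoint closest to the centre of `tm_window`, then longer window); the
#' best-ranked forward window that admits a feasible reverse window -- the
#' best-ranked window downstream of it giving a product length within
#' bounds and passing the [primer_qc()] screen -- yields the returned pair.
#' The selection is fully deterministic. By construction every input
#' sequence matches both primers with zero mismatches: the degenerate bases
#' absorb all observed variation, which is the annealing guarantee the
#' panel's primers were built under.
#'
#' @param aligned Equal-width character vector or `DNAStringSet`: the
#'   aligned ortholog sequences (gaps as `-`).
#' @param product_min,product_max Acceptable product length range (bp, in
#'   alignment coordinates).
#' @param max_degeneracy Per-primer degeneracy budget. Default 64.
#' @param tm_window Numeric length-2: acceptable annealing-temperature
#'   range (degC) that each primer's Tm range must intersect.
#' @param primer_len Candidate primer lengths to scan. Default 18:25.
#' @param qc_strict If `TRUE` (default), reject pairs flagged by
#'   [primer_qc()] (hairpin/self-dimer/cross-dimer).
#' @return A list with `fwd_seq`, `rev_seq` (reverse primer as synthesized,
#'   5' to 3'), `target_start`, `target_end`, `expected_len` (alignment
#'   coordinates), `degeneracy_fwd`, `degeneracy_rev`, and `qc` (a list of
#'   the two [primer_qc()] reports). Errors with the limiting constraint if
#'   no conserved window pair is feasible.
#' @export
design_primer_pair <- function(aligned, product_min, product_max,
                               max_degeneracy = 64L, tm_window = c(55, 68),
                               primer_len = 18:25, qc_strict = TRUE) {
  if (inherits(aligned, "DNAStringSet")) {
    aligned <- setNames(as.character(aligned), names(aligned))
  }
  if (length(aligned) < 2) {
    stop("need at least two aligned sequences", call. = FALSE)
  }
  widths <- unique(nchar(aligned))
  if (length(widths) != 1) {
    stop("aligned sequences must have equal width (found widths ",
         paste(widths, collapse = ", "), ")", call. = FALSE)
  }
  w <- widths
  chars <- do.call(rbind, strsplit(toupper(aligned), "", fixed = TRUE))
  cons <- column_consensus(chars, seq_len(w))      # NA at gapped columns
  deg <- rep(NA_real_, w)
  ok_col <- !is.na(cons)
  deg[ok_col] <- vapply(cons[ok_col], iupac_degeneracy, numeric(1))
  # enumerate candidate windows: gap-free, degeneracy within budget
  win <- list(start = integer(0), end = integer(0), degeneracy = numeric(0))
  for (len in primer_len) {
    if (len > w) next
    starts <- seq_len(w - len + 1L)
    for (s in starts) {
      d <- deg[s:(s + len - 1L)]
      if (anyNA(d)) next
      dd <- prod(d)
      if (dd > max_degeneracy) next
      win$start <- c(win$start, s)
      win$end <- c(win$end, s + len - 1L)
      win$degeneracy <- c(win$degeneracy, dd)
    }
  }
  if (!length(win$start)) {
    stop("no conserved window: no gap-free block of ",
         min(primer_len), "-", max(primer_len),
         " nt keeps degeneracy <= ", max_degeneracy, call. = FALSE)
  }
  tm_mid <- mean(tm_window)
  seqs <- vapply(seq_along(win$start), function(i) {
    paste(cons[win$start[i]:win$end[i]], collapse = "")
  }, character(1))
  tms <- vapply(seqs, primer_tm_range, numeric(2))
  in_tm <- tms["tm_max", ] >= tm_window[1] & tms["tm_min", ] <= tm_window[2]
  if (!any(in_tm)) {
    stop("no conserved window: no candidate window's Tm range intersects [",
         tm_window[1], ", ", tm_window[2], "] degC", call. = FALSE)
  }
  wdf <- data.frame(start = win$start[in_tm], end = win$end[in_tm],
                    degeneracy = win$degeneracy[in_tm],
                    seq = seqs[in_tm],
                    tm_dist = abs(colMeans(tms)[in_tm] - tm_mid),
                    stringsAsFactors = FALSE)
  wdf$len <- wdf$end - wdf$start + 1L
  wdf <- wdf[order(wdf$degeneracy, wdf$tm_dist, -wdf$len, wdf$start), ,
             drop = FALSE]
  feasible_len <- FALSE
  for (i in seq_len(nrow(wdf))) {
    plen <- wdf$end - wdf$start[i] + 1L
    cand_j <- which(wdf$start > wdf$end[i] &
                      plen >= product_min & plen <= product_max)
    if (!length(cand_j)) next
    feasible_len <- TRUE
    for (j in cand_j) {   # wdf already in rank order
      fseq <- wdf$seq[i]
      rseq <- reverse_complement(wdf$seq[j])
      qf <- primer_qc(fseq, partner = rseq)
      qr <- primer_qc(rseq, partner = fseq)
      if (qc_strict && (qf$hairpin_flag || qf$self_dimer_flag ||
                        isTRUE(qf$cross_dimer_flag) ||
                        qr$hairpin_flag || qr$self_dimer_flag)) next
      return(list(fwd_seq = fseq, rev_seq = rseq,
                  target_start = wdf$start[i], target_end = wdf$end[j],
                  expected_len = wdf$end[j] - wdf$start[i] + 1L,
                  degeneracy_fwd = wdf$degeneracy[i],
                  degeneracy_rev = wdf$degeneracy[j],
                  qc = list(fwd = qf, rev = qr)))
    }
  }
  stop("no conserved window: ",
       if (feasible_len) "every candidate pair failed the primer QC screen"
       else paste0("no window pair yields a product in [", product_min, ", ",
                   product_max, "] bp"),
       call. = FALSE)
}
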