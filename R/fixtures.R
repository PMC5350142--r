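# Seeded synthetic data: marker templates, phylogroup genomes, community
# mixtures, and pan-genomes with planted group-specific genes. Everything a
# test needs is generated in code; a given seed is bit-reproducible. Filler
# DNA is i.i.d. with configurable GC (default 0.60, typical of
# Pseudomonas); no repeat structure or read-level error model is simulated.

random_dna <- function(n, gc = 0.6) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate_positions <- function(chars, idx, rate) {
  if (!length(idx) || rate <= 0) return(chars)
  hit <- idx[stats::runif(length(idx)) < rate]
  for (p in hit) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  chars
}

#' Generate a synthetic template carrying one marker's primer sites
#'
#' Builds a sequence of length `target_end + flank` in which a seed-chosen
#' concrete expansion of the forward primer occupies the target interval's
#' start and the reverse complement of a seed-chosen expansion of the
#' reverse primer ends exactly at `target_end`; filler is seeded random DNA
#' at the requested GC. Point substitutions can be sprinkled outside
#' (`mutation_rate`) and inside (`mutation_rate_primer`) the primer
#' footprints.
#'
#' @param marker One row of a marker table (see [builtin_panel()]).
#' @param seed Integer seed; fully determines the output.
#' @param flank Extra bases appended after `target_end`. Default 100.
#' @param gc GC content of the filler DNA. Default 0.6.
#' @param mutation_rate,mutation_rate_primer Per-base substitution
#'   probabilities outside/inside the primer footprints. Defaults 0.
#' @return Named character vector of length 1 (the template; name =
#'   marker_id) with attribute `"truth"`: a list recording the planted
#'   footprints and chosen primer expansions.
#' @export
make_marker_template <- function(marker, seed = 1L, flank = 100L, gc = 0.6,
                                 mutation_rate = 0, mutation_rate_primer = 0) {
  marker <- as.list(marker)
  with_seed(seed, {
    fwd_opts <- iupac_expand(marker$fwd_seq, cap = 4096L)
    rev_opts <- iupac_expand(marker$rev_seq, cap = 4096L)
    fwd <- sample(fwd_opts, 1)
    rev <- sample(rev_opts, 1)
    flen <- nchar(fwd); rlen <- nchar(rev)
    total <- marker$target_end + flank
    fwd_start <- marker$target_start
    rev_start <- marker$target_end - rlen + 1L
    if (fwd_start + flen - 1L >= rev_start) {
      stop("target interval too short for the primer pair", call. = FALSE)
    }
    chars <- strsplit(random_dna(total, gc), "", fixed = TRUE)[[1]]
    chars[fwd_start:(fwd_start + flen - 1L)] <-
      strsplit(fwd, "", fixed = TRUE)[[1]]
    chars[rev_start:(rev_start + rlen - 1L)] <-
      strsplit(reverse_complement(rev), "", fixed = TRUE)[[1]]
    fp <- c(fwd_start:(fwd_start + flen - 1L), rev_start:(rev_start + rlen - 1L))
    chars <- mutate_positions(chars, setdiff(seq_len(total), fp),
                              mutation_rate)
    chars <- mutate_positions(chars, fp, mutation_rate_primer)
    out <- setNames(paste(chars, collapse = ""),
                    marker$marker_id %||% "template")
    attr(out, "truth") <- list(
      marker_id = marker$marker_id, fwd_oligo = fwd, rev_oligo = rev,
      fwd_start = fwd_start, fwd_end = fwd_start + flen - 1L,
      rev_start = rev_start, rev_end = marker$target_end,
      product_len = marker$target_end - marker$target_start + 1L)
    out
  })
}

#' Generate a synthetic phylogroup genome
#'
#' Emits one contig per planted marker: every marker the decision matrix
#' requires for `group` is planted, each variable marker is planted with
#' probability 0.5 (the plus-minus semantics absent any frequency data),
#' and forbidden markers are not planted -- their primers have no footprint
#' above chance in the random filler. A decoy contig of pure filler is
#' always included.
#'
#' @param group Phylogroup name (a column of `matrix`).
#' @param matrix Decision matrix.
#' @param markers Marker table.
#' @param seed Integer seed.
#' @param flank Flank length passed to [make_marker_template()].
#' @param gc Filler GC content.
#' @param mutation_rate,mutation_rate_primer Substitution rates outside/
#'   inside primer footprints. Defaults 0.02 and 0.
#' @param decoy_len Length of the marker-free decoy contig. Default 2000.
#' @return Named character vector of contigs with attribute `"truth"`:
#'   `list(group, planted)` where `planted` are the marker ids carried.
#' @export
make_group_genome <- function(group, matrix, markers, seed = 1L,
                              flank = 100L, gc = 0.6,
                              mutation_rate = 0.02,
                              mutation_rate_primer = 0,
                              decoy_len = 2000L) {
  if (!group %in% colnames(matrix)) {
    stop("unknown group '", group, "'", call. = FALSE)
  }
  req <- required_markers(matrix, group)
  var <- variable_markers(matrix, group)
  with_seed(seed, {
    planted <- c(req, var[stats::runif(length(var)) < 0.5])
  })
  planted <- markers$marker_id[markers$marker_id %in% planted]  # panel order
  contigs <- character(0)
  for (k in seq_along(planted)) {
    m <- markers[markers$marker_id == planted[k], ]
    tpl <- make_marker_template(m, seed = derive_seed(seed, k), flank = flank,
                                gc = gc, mutation_rate = mutation_rate,
                                mutation_rate_primer = mutation_rate_primer)
    contigs <- c(contigs, setNames(unname(tpl),
                                   paste0("contig_", planted[k])))
  }
  decoy <- with_seed(derive_seed(seed, 1000L), random_dna(decoy_len, gc))
  contigs <- c(contigs, setNames(decoy, "contig_decoy"))
  attr(contigs, "truth") <- list(group = group, planted = planted)
  contigs
}

#' Generate a pooled community sample
#'
#' Concatenates seeded phylogroup genomes according to integer-rounded
#' relative weights, emulating metagenomic DNA in which the observed marker
#' pattern is the union over the taxa present.
#'
#' @param groups Character vector of phylogroup names.
#' @param matrix,markers Panel as in [builtin_panel()].
#' @param weights Relative weights (>= 1 copy each). Default equal.
#' @param seed Integer seed.
#' @param ... Passed to [make_group_genome()].
#' @return Named character vector of contigs with attribute `"truth"`:
#'   `list(groups, union_pattern)` -- the union of planted markers.
#' @export
make_community <- function(groups, matrix, markers, weights = NULL,
                           seed = 1L, ...) {
  if (!length(groups)) stop("need at least one group", call. = FALSE)
  weights <- weights %||% rep(1, length(groups))
  stopifnot(length(weights) == length(groups))
  contigs <- character(0)
  planted <- character(0)
  for (i in seq_along(groups)) {
    g <- make_group_genome(groups[i], matrix, markers,
                           seed = derive_seed(seed, i), ...)
    truth <- attr(g, "truth")
    planted <- union(planted, truth$planted)
    copies <- max(1L, as.integer(round(weights[i])))
    for (cp in seq_len(copies)) {
      nm <- paste0(gsub("[. ]+", "_", groups[i]), "_c", cp, "_",
                   names(g))
      contigs <- c(contigs, setNames(unname(g), nm))
    }
  }
  attr(contigs, "truth") <- list(
    groups = groups,
    union_pattern = markers$marker_id[markers$marker_id %in% planted])
  contigs
}

#' Fabricate a pan-genome orthology table with planted group-specific genes
#'
#' Builds an [ortho_table()] over `n_groups` groups of `genomes_per_group`
#' genomes containing: shared-core orthogroups present in every genome,
#' noise orthogroups with arbitrary (never exactly group-core) genome sets,
#' and one planted group-core/absent-elsewhere orthogroup per group whose
#' members diverge by point substitutions at `1 - within_identity`.
#' Optionally a decoy copy of each planted gene, mutated down to
#' `decoy_identity`, is inserted into one out-group genome as its own
#' orthogroup -- visible only to the sequence-level re-screen, not to the
#' membership filter.
#'
#' @param n_groups Number of groups (>= 2). Default 3.
#' @param genomes_per_group Genomes per group. Default 3.
#' @param seed Integer seed.
#' @param planted_len Length of each planted gene (bp). Default 600.
#' @param within_identity Target within-group identity of planted members.
#'   Default 0.97.
#' @param n_core,n_noise Numbers of shared-core / noise orthogroups.
#' @param core_len,noise_len Gene lengths for those orthogroups.
#' @param decoy_identity If non-`NULL`, plant decoy copies at this identity.
#' @param gc Base composition of generated genes.
#' @return An [ortho_table()] with attribute `"truth"`: data frame
#'   (`group`, `orthogroup`) of the planted group-specific orthogroups.
#' @export
make_pangenome <- function(n_groups = 3L, genomes_per_group = 3L, seed = 1L,
                           planted_len = 600L, within_identity = 0.97,
                           n_core = 3L, n_noise = 6L,
                           core_len = 900L, noise_len = 700L,
                           decoy_identity = NULL, gc = 0.6) {
  stopifnot(n_groups >= 2, genomes_per_group >= 1)
  groups <- paste0("group", seq_len(n_groups))
  genomes <- data.frame(
    genome_id = paste0("g", seq_len(n_groups * genomes_per_group)),
    group = rep(groups, each = genomes_per_group),
    stringsAsFactors = FALSE)
  mem <- list()
  seqs <- character(0)
  add_member <- function(og, genome, seq) {
    cds <- paste0(og, "|", genome)
    mem[[length(mem) + 1L]] <<- data.frame(
      genome_id = genome, orthogroup = og, cds_id = cds,
      stringsAsFactors = FALSE)
    seqs[cds] <<- seq
  }
  mutate_to <- function(seq, identity) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    paste(mutate_positions(chars, seq_along(chars), 1 - identity),
          collapse = "")
  }
  with_seed(seed, {
    for (k in seq_len(n_core)) {
      og <- sprintf("OG_core_%02d", k)
      base <- random_dna(core_len, gc)
      for (g in genomes$genome_id) add_member(og, g, mutate_to(base, 0.98))
    }
    group_sets <- split(genomes$genome_id, genomes$group)
    for (k in seq_len(n_noise)) {
      og <- sprintf("OG_noise_%02d", k)
      repeat {
        carriers <- sample(genomes$genome_id,
                           sample(seq_len(nrow(genomes) - 1L), 1))
        # a noise orthogroup must never coincide with a full group's genome
        # set, or it would be an accidental planted marker
        if (!any(vapply(group_sets, setequal, logical(1), y = carriers))) break
      }
      base <- random_dna(noise_len, gc)
      for (g in carriers) add_member(og, g, mutate_to(base, 0.95))
    }
    truth <- data.frame(group = character(0), orthogroup = character(0),
                        stringsAsFactors = FALSE)
    for (gi in seq_along(groups)) {
      og <- sprintf("OG_planted_%s", groups[gi])
      base <- random_dna(planted_len, gc)
      for (g in group_sets[[groups[gi]]]) {
        add_member(og, g, mutate_to(base, within_identity))
      }
      truth <- rbind(truth, data.frame(group = groups[gi], orthogroup = og,
                                       stringsAsFactors = FALSE))
      if (!is.null(decoy_identity)) {
        host <- sample(setdiff(genomes$genome_id, group_sets[[groups[gi]]]), 1)
        add_member(paste0("OG_decoy_", groups[gi]), host,
                   mutate_to(base, decoy_identity))
      }
    }
    out <- ortho_table(genomes, do.call(rbind, mem), seqs)
    attr(out, "truth") <- truth
    out
  })
}

#' Write contigs (or any named sequences) to FASTA with a truth sidecar
#'
#' @param seqs Named character vector of sequences, typically from one of
#'   the generators; any `"truth"` attribute is written as a JSON sidecar
#'   next to the FASTA.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fixture_fasta <- function(seqs, path) {
  set <- DNAStringSet(unname(unlist(seqs)))
  names(set) <- names(seqs)
  writeXStringSet(set, path)
  truth <- attr(seqs, "truth")
  if (!is.null(truth)) {
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
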