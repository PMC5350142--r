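test_that("similarity screen reports identity, coverage and strand correctly", {
  set.seed(61)
  q <- random_acgt(200)
  self <- similarity_screen(q, c(same = q))
  expect_equal(self$identity, 1)
  expect_equal(self$coverage, 1)
  expect_true(self$hit)
  # reverse complement is found on the minus strand at full identity
  rc <- similarity_screen(q, c(flip = revcomp_chr(q)))
  expect_equal(rc$identity, 1)
  expect_equal(rc$strand, "-")
  # an unrelated random sequence never reaches a 0.7-identity hit
  rand <- similarity_screen(q, c(noise = random_acgt(200)), min_id = 0.7)
  expect_false(rand$hit)
  expect_lt(rand$identity * rand$coverage, 0.7)
})

test_that("group-specific discovery recovers exactly the planted genes", {
  pg <- make_pangenome(n_groups = 3, genomes_per_group = 3, seed = 62)
  truth <- attr(pg, "truth")
  for (g in unique(pg$genomes$group)) {
    cand <- find_group_specific(pg, g)
    accepted <- cand$orthogroup[cand$accepted]
    expect_equal(accepted, truth$orthogroup[truth$group == g])
    expect_true(all(cand$core_in_group & cand$absent_outside))
  }
  expect_error(find_group_specific(pg, "no-such-group"), "unknown group")
})

test_that("short planted genes are rejected by the length filter", {
  pg <- make_pangenome(n_groups = 2, genomes_per_group = 2, seed = 63,
                       planted_len = 300)
  cand <- find_group_specific(pg, "group1")
  expect_true(nrow(cand) >= 1)
  expect_false(any(cand$accepted))
  expect_false(any(cand$min_len_ok))
})

test_that("a near-identical out-group decoy fails the similarity re-screen", {
  pg <- make_pangenome(n_groups = 2, genomes_per_group = 2, seed = 64,
                       decoy_identity = 0.95)
  cand <- find_group_specific(pg, "group1")
  planted <- cand[grepl("planted", cand$orthogroup), ]
  expect_equal(nrow(planted), 1L)
  expect_false(planted$accepted)
  expect_gt(planted$cross_group_best_hit, 0.7)
  # membership-level flags still hold: only the sequence screen fails
  expect_true(planted$core_in_group && planted$absent_outside &&
                planted$min_len_ok)
  # a decoy diverged well below the threshold does not disqualify
  pg2 <- make_pangenome(n_groups = 2, genomes_per_group = 2, seed = 64,
                        decoy_identity = 0.45)
  cand2 <- find_group_specific(pg2, "group1")
  expect_true(cand2$accepted[grepl("planted", cand2$orthogroup)])
})

test_that("primer design on identical sequences returns exact substrings", {
  set.seed(65)
  base <- random_acgt(500, gc = 0.55)
  design <- design_primer_pair(rep(base, 3), product_min = 300,
                               product_max = 500)
  expect_equal(design$degeneracy_fwd, 1)
  expect_equal(design$degeneracy_rev, 1)
  # forward primer is a literal substring; reverse is a revcomp substring
  expect_equal(design$fwd_seq,
               substr(base, design$target_start,
                      design$target_start + nchar(design$fwd_seq) - 1))
  expect_equal(revcomp_chr(design$rev_seq),
               substr(base, design$target_end - nchar(design$rev_seq) + 1,
                      design$target_end))
  expect_true(design$expected_len >= 300 && design$expected_len <= 500)
})

test_that("designed primers place degenerate codes exactly at variable columns", {
  # orthologs that differ only where the published DGPf_0F shows R and Y;
  # the product bounds force the forward window onto the variant block, so
  # the designed primer must reproduce the published degenerate sequence
  fwd0 <- PANEL$markers$fwd_seq[1]
  variants <- iupac_expand(fwd0)         # 4 expansions: R x Y
  set.seed(66)
  right <- random_acgt(150, gc = 0.5)
  aligned <- vapply(variants, function(v) paste0(v, right), character(1))
  width <- nchar(aligned[1])             # 171
  design <- design_primer_pair(aligned, product_min = width,
                               product_max = width, tm_window = c(40, 80),
                               primer_len = 21, qc_strict = FALSE)
  expect_equal(design$fwd_seq, fwd0)
  expect_equal(design$degeneracy_fwd, 4)
  # independent column-wise oracle: consensus of the variant block
  block <- do.call(rbind, strsplit(aligned, ""))
  expect_equal(consensus_code(unique(block[, 15])), "R")
  expect_equal(consensus_code(unique(block[, 21])), "Y")
  expect_equal(consensus_code(unique(block[, 1])), substr(fwd0, 1, 1))
})

test_that("gapped columns block design and the failure names the constraint", {
  a <- "ACGTACGTAC-TACGTACGTACGTACGTACGTACGT"
  b <- "ACGTACGTACGTACGTACGTACGTACGTACGTACGT"
  expect_error(design_primer_pair(c(a, b), 10, 30, primer_len = 18:20),
               "no conserved window")
  # width mismatch and singleton inputs are rejected up front
  expect_error(design_primer_pair(c("ACGT", "ACG"), 2, 4), "equal width")
  expect_error(design_primer_pair("ACGT", 2, 4), "at least two")
})

test_that("accepted designs amplify every source sequence exactly once", {
  set.seed(67)
  base <- random_acgt(450, gc = 0.55)
  orthologs <- vapply(1:4, function(i) {
    ch <- strsplit(base, "")[[1]]
    idx <- sample(length(ch), 8)   # ~2% divergence
    for (p in idx) ch[p] <- sample(c("A", "C", "G", "T"), 1)
    paste(ch, collapse = "")
  }, character(1))
  design <- design_primer_pair(orthologs, product_min = 250,
                               product_max = 450, max_degeneracy = 256,
                               tm_window = c(45, 80))
  pair <- list(fwd_seq = design$fwd_seq, rev_seq = design$rev_seq,
               expected_len = design$expected_len, marker_id = "designed")
  for (s in orthologs) {
    amps <- predict_amplicons(pair, c(src = s),
                              ispcr_settings(max_mm = 0, max_mm_3p = 0))
    expect_equal(nrow(amps), 1L)
    expect_equal(amps$product_len, design$expected_len)
  }
})
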