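test_that("an exact substring is found with zero mismatches at its coordinates", {
  set.seed(21)
  tpl <- random_acgt(300)
  primer <- substr(tpl, 101, 122)
  sites <- find_binding_sites(primer, c(t1 = tpl))
  fwd <- sites[sites$strand == "+", ]
  expect_true(nrow(fwd) >= 1)
  expect_true(any(fwd$start == 101 & fwd$end == 122 &
                    fwd$mismatches_total == 0))
})

test_that("a planted expansion of a degenerate primer is recovered", {
  fwd6 <- PANEL$markers$fwd_seq[PANEL$markers$marker_id == "DGPf_6"]
  set.seed(22)
  expansion <- sample(iupac_expand(fwd6), 1)
  tpl <- paste0(random_acgt(27), expansion, random_acgt(60))
  sites <- find_binding_sites(fwd6, c(t1 = tpl))
  hit <- sites[sites$strand == "+" & sites$start == 28, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$mismatches_total, 0L)
  expect_equal(hit$end, 27L + nchar(fwd6))
})

test_that("a 3'-terminal mismatch is rejected when the 3' window is strict", {
  set.seed(23)
  tpl <- random_acgt(200)
  target <- substr(tpl, 90, 110)
  # corrupt the primer's 3'-terminal base so it cannot match its footprint
  last <- substr(target, 21, 21)
  bad <- paste0(substr(target, 1, 20),
                setdiff(c("A", "C", "G", "T"),
                        iupac_bases(last))[1])
  strict <- ispcr_settings(max_mm = 3, max_mm_3p = 0, window_3p = 5)
  sites <- find_binding_sites(bad, c(t1 = tpl), strict)
  expect_false(any(sites$strand == "+" & sites$start == 90))
  # the same footprint is admitted once a 3' mismatch is allowed
  relaxed <- ispcr_settings(max_mm = 3, max_mm_3p = 1, window_3p = 5)
  sites <- find_binding_sites(bad, c(t1 = tpl), relaxed)
  expect_true(any(sites$strand == "+" & sites$start == 90 &
                    sites$mismatches_3prime == 1))
})

test_that("empty and too-short templates yield empty site tables", {
  expect_equal(nrow(find_binding_sites("ACGTACGTACGT", c(t = ""))), 0L)
  expect_equal(nrow(find_binding_sites("ACGTACGTACGT", c(t = "ACG"))), 0L)
  expect_error(find_binding_sites("ACGTACGTACGT", c(t = "ACGTQACGTACGTA")),
               "invalid nucleotide")
})

test_that("site scan agrees exactly with a naive per-position oracle", {
  set.seed(24)
  for (rep in 1:12) {
    tpl <- random_acgt(sample(150:400, 1), gc = runif(1, 0.35, 0.65))
    primer <- random_iupac(sample(12:20, 1), degenerate_frac = 0.15)
    settings <- ispcr_settings(max_mm = sample(0:3, 1),
                               max_mm_3p = sample(0:1, 1),
                               window_3p = sample(3:6, 1))
    got <- find_binding_sites(primer, c(t = tpl), settings)
    want <- naive_sites(primer, tpl, settings)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$start, want$start)
      expect_equal(got$strand, want$strand)
      expect_equal(got$mismatches_total, want$mismatches_total)
      expect_equal(got$mismatches_3prime, want$mismatches_3prime)
    }
  }
})

test_that("site scan agrees with Biostrings matchPattern on total mismatches", {
  set.seed(25)
  for (rep in 1:6) {
    tpl <- random_acgt(500)
    primer <- random_iupac(16, degenerate_frac = 0.1)
    mm <- sample(0:2, 1)
    # disable the 3' filter to compare raw footprints
    settings <- ispcr_settings(max_mm = mm, max_mm_3p = mm, window_3p = 0)
    got <- find_binding_sites(primer, c(t = tpl), settings)
    ref <- Biostrings::matchPattern(Biostrings::DNAString(primer),
                                    Biostrings::DNAString(tpl),
                                    max.mismatch = mm, fixed = FALSE)
    ref_starts <- IRanges::start(ref)
    ref_starts <- ref_starts[ref_starts >= 1 &
                               ref_starts + nchar(primer) - 1 <= nchar(tpl)]
    expect_equal(got$start[got$strand == "+"], sort(ref_starts))
  }
})

test_that("synthetic marker templates produce the published product lengths", {
  # printed coordinate arithmetic: product spans both footprints inclusive
  for (id in c("DGPf_3", "DGPf_5")) {
    m <- PANEL$markers[PANEL$markers$marker_id == id, ]
    tpl <- make_marker_template(m, seed = 31, flank = 60)
    amps <- predict_amplicons(m, setNames(unname(tpl), "tpl"))
    expect_equal(nrow(amps), 1L)
    expect_equal(amps$product_len, m$expected_len)
    expect_equal(amps$product_start, m$target_start)
    expect_equal(amps$product_end, m$target_end)
    expect_true(amps$within_expected)
  }
})

test_that("no product is predicted without both primers in orientation", {
  m <- PANEL$markers[PANEL$markers$marker_id == "DGPf_2", ]
  tpl <- make_marker_template(m, seed = 32, flank = 40)
  # truncate before the reverse footprint: forward site only
  truncated <- substr(unname(tpl), 1, m$target_end - 50)
  amps <- predict_amplicons(m, c(t = truncated))
  expect_equal(nrow(amps), 0L)
})

test_that("amplicon predictions are strand-symmetric", {
  for (seed in 33:35) {
    m <- PANEL$markers[PANEL$markers$marker_id == "DGPf_7", ]
    tpl <- unname(make_marker_template(m, seed = seed, flank = 80))
    fwd <- predict_amplicons(m, c(t = tpl))
    rev <- predict_amplicons(m, c(t = revcomp_chr(tpl)))
    expect_equal(nrow(fwd), nrow(rev))
    expect_equal(sort(fwd$product_len), sort(rev$product_len))
  }
})

test_that("stringency is monotone: more mismatch budget, never fewer sites", {
  set.seed(36)
  tpl <- random_acgt(600)
  primer <- random_iupac(15, degenerate_frac = 0.2)
  prev <- -1L
  for (mm in 0:3) {
    s <- ispcr_settings(max_mm = mm, max_mm_3p = mm, window_3p = 5)
    n <- nrow(find_binding_sites(primer, c(t = tpl), s))
    expect_gte(n, prev)
    prev <- n
  }
  # tightening the product-length window never adds amplicons
  m <- PANEL$markers[PANEL$markers$marker_id == "DGPf_0", ]
  tpl <- make_marker_template(m, seed = 37, flank = 100)
  wide <- predict_amplicons(m, setNames(unname(tpl), "t"),
                            ispcr_settings(min_len = 50, max_len = 5000))
  narrow <- predict_amplicons(m, setNames(unname(tpl), "t"),
                              ispcr_settings(min_len = 600, max_len = 620))
  expect_lte(nrow(narrow), nrow(wide))
  expect_true(all(narrow$product_len %in% wide$product_len))
})

test_that("N-strict mode suppresses sites created by template N runs", {
  set.seed(39)
  primer <- "ACGTACGTACGTACGTACGT"
  tpl <- paste0(random_acgt(40), strrep("N", 30), random_acgt(40))
  lenient <- find_binding_sites(primer, c(t = tpl),
                                ispcr_settings(max_mm = 0, max_mm_3p = 0))
  expect_gt(nrow(lenient), 0)
  strict <- find_binding_sites(primer, c(t = tpl),
                               ispcr_settings(max_mm = 0, max_mm_3p = 0,
                                              n_strict = TRUE))
  expect_equal(nrow(strict), 0L)
})

test_that("genome profiling recovers exactly the planted marker set", {
  # the P. fluorescens-group signature: DGPf_5 and DGPf_7
  sig <- canonical_signatures(PANEL$matrix)[["P. fluorescens"]]
  contigs <- unlist(lapply(sig, function(id) {
    m <- PANEL$markers[PANEL$markers$marker_id == id, ]
    setNames(unname(make_marker_template(m, seed = 38, flank = 90)), id)
  }))
  profile <- profile_genome(PANEL$markers, contigs)
  expect_setequal(profile$present, c("DGPf_5", "DGPf_7"))
  expect_setequal(profile$absent, setdiff(MARKER_IDS, sig))
  evid <- attr(profile, "amplicons")
  expect_true(all(c("DGPf_5", "DGPf_7") %in% evid$marker_id))
  # empty genome: everything absent
  empty <- profile_genome(PANEL$markers, c(c1 = ""))
  expect_length(empty$present, 0)
  expect_setequal(empty$absent, MARKER_IDS)
})
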