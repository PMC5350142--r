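test_that("reference strain patterns classify to their published phylogroups", {
  pats <- read_pattern_table(
    system.file("extdata", "table3_patterns.tsv", package = "pflutype"),
    extra_cols = "expected_group")
  expect_length(pats, 13)
  for (p in pats) {
    r <- classify_pattern(p, PANEL$matrix)
    expect_equal(r$assigned_group, attr(p, "annotations")$expected_group,
                 label = p$sample_id)
  }
  # the out-of-complex control with a lone DGPf_2 positive stays unassigned
  kt <- classify_pattern(full_pattern("DGPf_2", "KT2440"), PANEL$matrix)
  expect_equal(kt$assigned_group, "none")
  expect_equal(kt$n_positive, 1L)
})

test_that("field isolate patterns classify to their published phylogroups", {
  pats <- read_pattern_table(
    system.file("extdata", "table4_isolates.tsv", package = "pflutype"),
    extra_cols = "expected_group")
  expect_length(pats, 19)
  got <- vapply(pats, function(p) {
    classify_pattern(p, PANEL$matrix)$assigned_group
  }, character(1))
  want <- vapply(pats, function(p) attr(p, "annotations")$expected_group,
                 character(1))
  expect_equal(got, want)
  # published headcounts: 6 koreensis, 6 jessenii, 5 fluorescens, 2 corrugata
  expect_equal(as.integer(table(got)[c("P. koreensis", "P. jessenii",
                                       "P. fluorescens", "P. corrugata")]),
               c(6L, 6L, 5L, 2L))
})

test_that("strict matching semantics: vetoes, support and conflicts", {
  # a forbidden positive vetoes an otherwise matching group
  r <- classify_pattern(full_pattern(c("DGPf_0", "DGPf_1", "DGPf_2")),
                        PANEL$matrix)
  expect_equal(r$assigned_group, "none")
  veto <- r$conflicts[r$conflicts$group == "P. corrugata", ]
  expect_true(any(veto$marker == "DGPf_2" &
                    veto$reason == "forbidden marker present"))
  # an empty pattern is unassigned
  expect_equal(classify_pattern(full_pattern(character(0)),
                                PANEL$matrix)$assigned_group, "none")
  # variable markers support but never gate: protegens with and without them
  with_var <- classify_pattern(full_pattern(c("DGPf_2", "DGPf_4", "DGPf_6")),
                               PANEL$matrix)
  without <- classify_pattern(full_pattern(c("DGPf_2", "DGPf_4")),
                              PANEL$matrix)
  expect_equal(with_var$assigned_group, "P. protegens")
  expect_equal(without$assigned_group, "P. protegens")
  expect_setequal(with_var$supporting_markers,
                  c("DGPf_2", "DGPf_4", "DGPf_6"))
  # partial patterns are redirected to deconvolution
  expect_error(classify_pattern(marker_pattern("x", present = "DGPf_2"),
                                PANEL$matrix), "deconvolve")
  # lenient mode names the nearest group but strict never does
  near <- marker_pattern("y", present = c("DGPf_5"),
                         absent = setdiff(MARKER_IDS, "DGPf_5"))
  expect_equal(classify_pattern(near, PANEL$matrix)$assigned_group, "none")
  lenient <- classify_pattern(near, PANEL$matrix, mode = "lenient")
  expect_true(lenient$assigned_group %in% c("P. gessardii", "P. fluorescens"))
})

test_that("environmental patterns deconvolve to the published compatible sets", {
  pats <- read_pattern_table(
    system.file("extdata", "table4_environmental.tsv", package = "pflutype"),
    extra_cols = "expected_groups")
  expect_length(pats, 3)
  for (p in pats) {
    d <- deconvolve_pattern(p, PANEL$matrix)
    want <- strsplit(attr(p, "annotations")$expected_groups, ";")[[1]]
    expect_setequal(d$compatible_groups, want)
    expect_length(d$unexplained_positives, 0)
    # the two partitions cover all eight groups exactly once
    expect_setequal(c(d$compatible_groups, d$excluded_groups$group), GROUPS)
    # every exclusion names a genuinely required, genuinely missing marker
    for (k in seq_len(nrow(d$excluded_groups))) {
      g <- d$excluded_groups$group[k]; m <- d$excluded_groups$missing_marker[k]
      expect_equal(unname(PANEL$matrix[m, g]), marker_states()[["required"]])
      expect_false(m %in% p$present)
    }
  }
  # no positives: everything excluded
  d0 <- deconvolve_pattern(marker_pattern("blank"), PANEL$matrix)
  expect_length(d0$compatible_groups, 0)
  expect_equal(nrow(d0$excluded_groups), 8L)
})

test_that("deconvolution is monotone and consistent with classification", {
  set.seed(51)
  for (k in 1:25) {
    present <- sample(MARKER_IDS, sample(0:9, 1))
    pat <- full_pattern(present)
    cls <- classify_pattern(pat, PANEL$matrix)
    dec <- deconvolve_pattern(pat, PANEL$matrix)
    if (cls$assigned_group != "none") {
      expect_true(cls$assigned_group %in% dec$compatible_groups)
    }
    # adding one marker never shrinks the compatible set
    extra <- setdiff(MARKER_IDS, present)
    if (length(extra)) {
      grown <- deconvolve_pattern(full_pattern(c(present, extra[1])),
                                  PANEL$matrix)
      expect_true(all(dec$compatible_groups %in% grown$compatible_groups))
    }
  }
  # absence-uninformative mode: untested required markers do not exclude
  part <- marker_pattern("partial", present = c("DGPf_5", "DGPf_7"),
                         absent = "DGPf_2")
  d <- deconvolve_pattern(part, PANEL$matrix, absence_informative = FALSE)
  expect_true("P. fluorescens" %in% d$compatible_groups)
  expect_true("P. gessardii" %in% d$compatible_groups)  # DGPf_6 untested
  expect_false("P. koreensis" %in% d$compatible_groups) # DGPf_2 tested neg
})

test_that("exhaustive enumeration: unique assignments and eight canonical signatures", {
  tab <- enumerate_assignments(PANEL$matrix)
  expect_equal(nrow(tab), 512L)
  expect_equal(nrow(attr(tab, "ambiguous")), 0L)
  expect_true(all(tab$n_matching <= 1L))
  # independent set-algebra oracle, pattern by pattern
  for (i in sample(seq_len(512), 60)) {
    present <- strsplit(tab$pattern[i], ",")[[1]]
    ok <- vapply(GROUPS, function(g) {
      req <- rownames(PANEL$matrix)[PANEL$matrix[, g] == "+"]
      forb <- rownames(PANEL$matrix)[PANEL$matrix[, g] == "-"]
      all(req %in% present) && !any(forb %in% present)
    }, logical(1))
    want <- if (sum(ok) == 1 && length(present) >= 2) GROUPS[ok] else "none"
    expect_equal(tab$assigned_group[i], want)
  }
  # exactly eight patterns equal a canonical signature
  sigs <- canonical_signatures(PANEL$matrix)
  sig_keys <- vapply(sigs, function(s) paste(sort(s), collapse = ","),
                     character(1))
  expect_length(unique(sig_keys), 8)
  tab_keys <- vapply(strsplit(tab$pattern, ","), function(s) {
    paste(sort(s), collapse = ",")
  }, character(1))
  expect_equal(sum(tab_keys %in% sig_keys), 8L)
  # each canonical signature classifies to its own group
  for (g in GROUPS) {
    expect_equal(classify_pattern(full_pattern(sigs[[g]]),
                                  PANEL$matrix)$assigned_group, g)
  }
})

test_that("an engineered matrix ambiguity is detected by brute force", {
  # relaxing mandelii's veto on DGPf_2 makes {DGPf_0, DGPf_2, DGPf_3}
  # satisfy both P. jessenii (requires 2,3) and P. mandelii (requires 0,3)
  mat <- PANEL$matrix
  mat["DGPf_2", "P. mandelii"] <- marker_states()[["variable"]]
  tab <- suppressWarnings(enumerate_assignments(mat))
  amb <- attr(tab, "ambiguous")
  expect_gt(nrow(amb), 0)
  keys <- vapply(strsplit(amb$pattern, ","), function(s) {
    paste(sort(s), collapse = ",")
  }, character(1))
  expect_true("DGPf_0,DGPf_2,DGPf_3" %in% keys)
  expect_warning(enumerate_assignments(mat), "ambiguous")
  # validate_panel reports it, and classify refuses to pick a side
  expect_true(any(grepl("ambiguous", validate_panel(PANEL$markers, mat))))
  expect_error(classify_pattern(
    full_pattern(c("DGPf_0", "DGPf_2", "DGPf_3")), mat), "ambiguous")
})

test_that("accuracy accounting reproduces the published validation figures", {
  acc <- accuracy_summary(421, 225, 218, 0)
  expect_equal(acc$pct_accuracy, 98.34)     # 7 of 421 misidentified
  expect_equal(acc$pct_concordant, 96.9)    # 218 of 225
  expect_equal(acc$pct_false_positive, 3.1) # 7 of 225
  expect_equal(acc$n_false_positive, 7L)
  expect_equal(acc$n_concordant + acc$n_false_positive, acc$n_identified)
  # degenerate edges
  expect_equal(accuracy_summary(50, 50, 50, 0)$pct_accuracy, 100)
  expect_error(accuracy_summary(10, 11, 5, 0), "n_identified")
  expect_error(accuracy_summary(10, 5, 6, 0), "n_concordant")
})
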