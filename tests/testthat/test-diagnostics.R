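test_that("exon identity matrices are exact, symmetric and unit-diagonal", {
  s <- c(a = "AAAATTTT", b = "AAAATTTT")
  plan <- exon_plan(c(4, 4), c("1", "2"))
  idm <- exon_identity(s, plan)
  expect_equal(idm[["1"]][1, 2], 1.0)
  expect_equal(idm[["2"]][1, 2], 1.0)

  # one mismatch in a 100-nt exon -> 0.99
  x <- strrep("A", 100); y <- paste0(strrep("A", 99), "C")
  idm2 <- exon_identity(c(a = x, b = y), exon_plan(100, "1"))
  expect_equal(idm2[["1"]]["a", "b"], 0.99)

  # 4-gene toy equals the brute-force position scan
  fam <- tiny_family(n = 4, seed = 17)
  idm3 <- exon_identity(fam)
  rng <- exon_ranges(fam$exon_plan)
  for (e in seq_len(nrow(rng))) {
    m <- idm3[[rng$exon[e]]]
    expect_true(isSymmetric(m))
    expect_equal(unname(diag(m)), rep(1, 4))
    for (a in 1:4) for (b in 1:4) {
      expect_equal(m[a, b],
                   naive_identity(fam$sequences[[a]], fam$sequences[[b]],
                                  rng$start[e] + 1L, rng$end[e]))
    }
  }
})

test_that("sister genes are identical at conserved exons in the preset", {
  fam <- kir_preset_family(33)
  idm <- exon_identity(fam)
  for (ex in c("1", "2", "6", "7", "8"))
    expect_equal(idm[[ex]]["KIR3DL1", "KIR3DS1"], 1.0)
  for (ex in c("3", "4", "5"))
    expect_lt(idm[[ex]]["KIR3DL1", "KIR3DS1"], 1.0)
})

test_that("diagnostic positions are exactly the non-unanimous columns", {
  expect_warning(find_diagnostic_positions(c(a = "ACGT")), "single")
  dp0 <- find_diagnostic_positions(c(a = "ACGT", b = "ACGT"))
  expect_equal(nrow(dp0), 0L)

  dp1 <- find_diagnostic_positions(c(a = "ACGTACGT", b = "ACGAACGT"))
  expect_equal(unique(dp1$pos), 3L)
  expect_setequal(dp1$diagnostic_for, c("a", "b"))

  # 3-sequence group equals a brute-force column scan
  set.seed(5)
  fam <- tiny_family(n = 3, seed = 23, id = 0.9)
  seqs <- fam$sequences
  dp <- find_diagnostic_positions(seqs)
  mat <- do.call(cbind, strsplit(seqs, ""))
  brute <- which(apply(mat, 1, function(r) length(unique(r)) > 1)) - 1L
  expect_identical(sort(unique(dp$pos)), brute)
  # base support maps are correct
  for (i in seq_len(nrow(dp))) {
    carriers <- strsplit(dp$members[i], ",")[[1]]
    expect_setequal(carriers,
                    names(seqs)[mat[dp$pos[i] + 1L, ] == dp$base[i]])
  }
})

test_that("error-free locus reads classify to their true source", {
  fam <- kir_preset_family(44)
  al <- generate_alleles(fam, seed = 1)
  gt <- all_present_genotype(fam, al)
  tr <- simulate_expression(gt, 150, seed = 2)
  rd <- simulate_reads(tr, gt, al, read_length = 90, error_rate = 0,
                       start_model = list(type = "uniform"), seed = 3)
  grp <- c("KIR3DL1", "KIR3DS1")
  dp <- find_diagnostic_positions(fam$sequences[grp])
  locus_reads <- rd[rd$true_gene %in% grp, ]
  comp <- classify_locus_reads(
    data.frame(read_id = locus_reads$read_id,
               start = locus_reads$true_start,
               sequence = locus_reads$sequence),
    dp)
  expect_equal(sum(comp$fractions), 1.0)
  # zero misclassifications; conflicts impossible without errors
  calls <- comp$per_read$call
  truth <- locus_reads$true_gene
  classified <- calls %in% grp
  expect_true(any(classified))
  expect_true(all(calls[classified] == truth[classified]))
  expect_equal(comp$fractions[["conflicting"]], 0)
  # a read covering no diagnostic position is uninformative
  clean <- data.frame(read_id = "x", start = 0L,
                      sequence = substr(fam$sequences[["KIR3DL1"]], 1, 30))
  expect_equal(classify_locus_reads(clean, dp)$per_read$call,
               "uninformative")
  # missing offsets are rejected
  expect_error(classify_locus_reads(
    data.frame(read_id = "x", start = NA_integer_, sequence = "ACGT"), dp),
    "offset")
})

test_that("sink prediction finds homolog sinks and unmapped losses", {
  fam <- kir_preset_family(55)
  rr <- restricted_reference(fam)
  s1 <- predict_sink("KIR3DS1", fam, rr)
  expect_equal(s1$sink, "KIR3DL1")
  expect_gte(s1$max_identity, s1$threshold)
  l5 <- predict_sink("KIR2DL5", fam, rr)
  expect_equal(l5$sink, "UNMAPPED")
  expect_lt(l5$max_identity, l5$threshold)
  expect_error(predict_sink("KIR2DL1", fam, rr), "present in the reference")
  expect_error(predict_sink("KIR3DS1", fam, rr, identity_window = 1e6),
               "window")
})

test_that("decisive sink predictions agree with simulated read fates", {
  res <- preset_result()
  asg <- res$assign_restricted
  decisive <- Filter(function(p) p$decisive, res$sink_predictions)
  # the preset's sister genes and the distant gene all have decisive fates
  expect_gte(length(decisive), 7L)
  for (p in decisive) {
    mine <- res$reads$true_gene == p$absent_gene
    lab <- ifelse(asg$status[mine] == "unique", asg$gene_id[mine],
                  asg$status[mine])
    majority <- names(sort(table(lab), decreasing = TRUE))[1]
    expect_equal(majority,
                 if (p$sink == "UNMAPPED") "unmapped" else p$sink,
                 label = sprintf("majority fate of %s", p$absent_gene))
  }
})
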