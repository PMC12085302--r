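mini_assignments <- function(read_ids, status, gene) {
  out <- data.frame(read_id = read_ids, status = status, gene_id = gene,
                    best_score = ifelse(status == "unmapped", NA, 50L),
                    margin = NA_real_, stringsAsFactors = FALSE)
  class(out) <- c("assignment_table", "data.frame")
  out
}

test_that("UMI counting collapses exact triples and needs valid names", {
  ids <- c("r1:BC1:U1", "r2:BC1:U1", "r3:BC1:U2", "r4:BC2:U1")
  asg <- mini_assignments(ids, rep("unique", 4), c("g1", "g1", "g1", "g2"))
  cm <- count_umis(asg)
  expect_equal(sum(cm$matrix), 3)          # r1/r2 share a triple
  expect_equal(unname(cm$matrix["BC1", "g1"]), 2)
  expect_equal(unname(cm$matrix["BC2", "g2"]), 1)
  # multimapped-only input yields an all-zero matrix
  mm <- mini_assignments(ids, rep("multimapped", 4), NA_character_)
  expect_equal(sum(count_umis(mm, countable = c("g1", "g2"))$matrix), 0)
  expect_error(count_umis(mini_assignments("bad_name", "unique", "g1")),
               "read name")
})

test_that("matrix total equals the distinct-triple count (brute force)", {
  res <- preset_result()
  asg <- res$assign_full
  cm <- res$counts_full
  parts <- strsplit(asg$read_id, ":", fixed = TRUE)
  u <- asg$status == "unique"
  triples <- unique(paste(vapply(parts, `[`, character(1), 2)[u],
                          vapply(parts, `[`, character(1), 3)[u],
                          asg$gene_id[u]))
  expect_equal(sum(cm$matrix), length(triples))
  # countable restriction: the filtered restricted arm has 6 gene columns
  expect_equal(ncol(res$counts_restricted$matrix), 6L)
  expect_false("KIR2DS4" %in% colnames(res$counts_restricted$matrix))
})

test_that("Matrix Market export round-trips the count matrix", {
  res <- preset_result()
  d <- tempfile()
  write_counts_mtx(res$counts_full, d)
  m <- Matrix::readMM(file.path(d, "matrix.mtx"))
  expect_equal(dim(m), rev(dim(res$counts_full$matrix)))
  expect_equal(sum(m), sum(res$counts_full$matrix))
  expect_equal(readLines(file.path(d, "features.tsv")),
               colnames(res$counts_full$matrix))
})

test_that("identical assignment tables give a purely diagonal flow", {
  ids <- sprintf("r%d:BC:U%d", 1:6, 1:6)
  a <- mini_assignments(ids, c(rep("unique", 4), "multimapped", "unmapped"),
                        c("g1", "g1", "g2", "g2", NA, NA))
  fl <- compare_references(a, a)
  m <- fl$matrix
  expect_equal(sum(m), 6)
  expect_equal(sum(diag(m)), 6)
  expect_equal(fl$signed_change, 0)
  b <- a; b$read_id[1] <- "rX:BC:U9"
  expect_error(compare_references(a, b), "different read ids")
})

test_that("flow marginals conserve reads and record the count change", {
  res <- preset_result()
  fl <- res$flow
  expect_equal(sum(rowSums(fl$matrix)), nrow(res$reads))
  expect_equal(sum(colSums(fl$matrix)), nrow(res$reads))
  ua <- sum(res$assign_restricted$status == "unique")
  ub <- sum(res$assign_full$status == "unique")
  expect_equal(fl$signed_change, (ub - ua) / ua)
})

test_that("misassignment report is sound on truthful assignments", {
  # error-free, full reference, all genes present: unique implies true
  fam <- tiny_family(n = 4, seed = 31)
  al <- generate_alleles(fam, seed = 1)
  gt <- all_present_genotype(fam, al)
  tr <- simulate_expression(gt, 40, seed = 2)
  rd <- simulate_reads(tr, gt, al, read_length = 60, error_rate = 0, seed = 3)
  asg <- align_all(rd, build_reference(fam), k = 15)
  rep <- misassignment_report(asg, rd)
  expect_equal(rep$misassigned_fraction, 0)
  # verified read-by-read against the oracle
  orc <- oracle_assign(rd$sequence, build_reference(fam),
                       read_ids = rd$read_id)
  u <- orc$status == "unique"
  expect_true(all(orc$gene_id[u] == rd$true_gene[u]))
  # per-true-gene label distributions each sum to 1
  expect_true(all(abs(rowSums(rep$by_true_gene) - 1) < 1e-12))
  # empty input gives an empty report
  expect_equal(misassignment_report(asg[0, ], rd)$n_reads, 0L)
})

test_that("inhibitory overcount is positive when activating reads sink", {
  res <- preset_result()
  classes <- setNames(res$family$genes$receptor_class,
                      res$family$genes$gene_id)
  rep_r <- misassignment_report(res$assign_restricted, res$reads, classes)
  expect_gt(rep_r$inhibitory_overcount, 0)
})

test_that("co-expression patterns match brute-force enumeration", {
  res <- preset_result()
  pats <- coexpression_patterns(res$counts_full, min_count = 1)
  m <- as.matrix(res$counts_full$matrix)
  sets <- apply(m >= 1, 1, function(r) paste(colnames(m)[r], collapse = "+"))
  sets <- sets[nzchar(sets)]
  expect_equal(sum(pats$n_cells), length(sets))
  brute <- sort(table(sets), decreasing = TRUE)
  expect_equal(setNames(pats$n_cells, pats$pattern)[names(brute)],
               setNames(as.integer(brute), names(brute)))
  # ranking is by cell count with lexicographic tie-break
  expect_true(all(diff(pats$n_cells) <= 0))
  # degenerate threshold
  expect_equal(nrow(coexpression_patterns(res$counts_full,
                                          min_count = 10000L)), 0L)
})

test_that("genotype inference thresholds behave at the edges", {
  res <- preset_result()
  empty <- res$counts_full
  empty$matrix <- empty$matrix * 0
  expect_false(any(infer_genotype(empty)))
  expect_error(infer_genotype(res$counts_full, min_umis = 0), ">= 1")
  # restricted reference on a donor with B genes: activating analogs
  # cannot be called (false negatives forced by the reference)
  calls_r <- infer_genotype(res$counts_restricted)
  b_act <- res$family$genes$gene_id[
    res$family$genes$receptor_class == "activating" &
      res$family$genes$haplotype_assoc == "B_associated"]
  expect_false(any(b_act %in% names(calls_r)[calls_r]))
})
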