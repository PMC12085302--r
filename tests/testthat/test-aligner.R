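test_that("k-mer index postings are complete and exact", {
  fam <- tiny_family(n = 1)
  ref <- build_reference(fam)
  idx <- build_kmer_index(ref, k = 15)
  L <- plan_length(fam$exon_plan)
  expect_equal(idx$n_postings, L - 15 + 1)

  # two identical transcripts: every k-mer occurs on both
  fam2 <- generate_family(2, tiny_plan(), tiny_profile(1.0), seed = 1)
  idx2 <- build_kmer_index(build_reference(fam2), k = 15)
  po <- kmer_postings(idx2)
  per_kmer <- table(po$kmer)
  expect_true(all(per_kmer >= 2))

  # postings verified against a naive scan on a 3-transcript toy
  fam3 <- tiny_family(n = 3, seed = 9)
  ref3 <- build_reference(fam3)
  idx3 <- build_kmer_index(ref3, k = 12)
  po3 <- kmer_postings(idx3)
  naive <- do.call(rbind, lapply(seq_len(3), function(t) {
    s <- ref3$transcripts$sequence[t]
    data.frame(kmer = substring(s, 1:(nchar(s) - 11), 12:nchar(s)),
               transcript_id = ref3$transcripts$transcript_id[t],
               offset = 0:(nchar(s) - 12), stringsAsFactors = FALSE)
  }))
  key <- function(d) sort(paste(d$kmer, d$transcript_id, d$offset))
  expect_identical(key(po3), key(naive))
})

test_that("exact-substring reads get a single perfect best hit", {
  fam <- tiny_family(n = 3, seed = 4)
  ref <- build_reference(fam)
  idx <- build_kmer_index(ref, k = 15)
  rd <- substr(fam$sequences[["G02"]], 31, 80)
  hits <- align_read(rd, idx)
  best <- hits[which.max(hits$score), ]
  expect_equal(best$gene_id, "G02")
  expect_equal(best$score, 50L)
  expect_equal(best$start, 30L)
  expect_equal(best$n_mismatches, 0L)
})

test_that("dissimilar reads fall below the acceptance threshold", {
  fam <- tiny_family(n = 3, seed = 4)
  ref <- build_reference(fam)
  idx <- build_kmer_index(ref, k = 15)
  set.seed(99)
  rd <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
              collapse = "")
  # oracle confirms the read is genuinely sub-threshold everywhere
  expect_equal(nrow(oracle_align(rd, ref)), 0L)
  expect_equal(nrow(align_read(rd, idx)), 0L)
  expect_equal(assign_read(align_read(rd, idx))$status, "unmapped")
})

test_that("reads from a shared exon tie across both genes", {
  fam <- tiny_family(n = 2, seed = 6)
  # make exon 1 of G02 identical to G01 via an allele override, then use
  # the override allele as G02's reference transcript
  al <- generate_alleles(fam, seed = 1, shared_exon_overrides = list(
    list(gene_id = "G02", allele_name = "*002", from_gene = "G01",
         exons = "1")))
  ref <- build_reference(fam, allele_policy = "named_allele_per_gene",
                         alleles = al,
                         named_alleles = c(G01 = "*001", G02 = "*002"))
  idx <- build_kmer_index(ref, k = 15)
  rd <- substr(fam$sequences[["G01"]], 1, 50)  # inside shared exon 1
  hits <- align_read(rd, idx)
  expect_equal(nrow(hits), 2L)
  expect_equal(unique(hits$score), 50L)
  # the oracle agrees the scores are tied
  oh <- oracle_align(rd, ref)
  expect_equal(unique(oh$score), 50L)
  expect_equal(assign_read(hits)$status, "multimapped")
})

test_that("the tie rule distinguishes genes from alleles", {
  one_hit <- data.frame(transcript_id = "A", gene_id = "A", start = 0L,
                        score = 50L, n_mismatches = 0L)
  expect_equal(assign_read(one_hit)$status, "unique")
  two_genes <- rbind(one_hit,
                     data.frame(transcript_id = "B", gene_id = "B",
                                start = 0L, score = 50L, n_mismatches = 0L))
  expect_equal(assign_read(two_genes)$status, "multimapped")
  # two alleles of one gene are one gene
  two_alleles <- two_genes
  two_alleles$gene_id <- "A"
  a <- assign_read(two_alleles)
  expect_equal(a$status, "unique")
  expect_equal(a$gene_id, "A")
})

test_that("alignment conserves reads across statuses", {
  fam <- tiny_family(n = 4, seed = 10)
  al <- generate_alleles(fam, seed = 1)
  gt <- all_present_genotype(fam, al)
  tr <- simulate_expression(gt, 50, seed = 2)
  rd <- simulate_reads(tr, gt, al, read_length = 60, error_rate = 0.01,
                       seed = 3)
  asg <- align_all(rd, build_reference(fam), k = 15)
  expect_equal(nrow(asg), nrow(rd))
  expect_equal(sum(attr(asg, "status_counts")), nrow(rd))
  expect_true(all(is.na(asg$gene_id[asg$status != "unique"])))
  expect_true(all(!is.na(asg$gene_id[asg$status == "unique"])))
  # empty input gives an empty table
  empty <- align_all(character(0), build_reference(fam), k = 15)
  expect_equal(nrow(empty), 0L)
})

test_that("a superset reference never lowers a read's best score", {
  fam <- tiny_family(n = 5, seed = 12)
  al <- generate_alleles(fam, seed = 1)
  gt <- all_present_genotype(fam, al)
  tr <- simulate_expression(gt, 30, seed = 2)
  rd <- simulate_reads(tr, gt, al, read_length = 60, error_rate = 0.02,
                       seed = 3)
  sub <- build_reference(fam, gene_subset = c("G01", "G02"))
  sup <- build_reference(fam)
  a_sub <- align_all(rd, sub, k = 15)
  a_sup <- align_all(rd, sup, k = 15)
  both <- !is.na(a_sub$best_score)
  expect_true(all(a_sup$best_score[both] >= a_sub$best_score[both]))
})

test_that("error-free reads always seed on their true transcript", {
  fam <- tiny_family(n = 4, seed = 13)
  al <- generate_alleles(fam, seed = 1)
  gt <- all_present_genotype(fam, al)
  tr <- simulate_expression(gt, 40, seed = 2)
  rd <- simulate_reads(tr, gt, al, read_length = 50, error_rate = 0, seed = 3)
  ref <- build_reference(fam)
  idx <- build_kmer_index(ref, k = 21)
  for (i in sample(nrow(rd), 25)) {
    hits <- align_read(rd$sequence[i], idx)
    own <- hits[hits$gene_id == rd$true_gene[i], ]
    expect_equal(nrow(own), 1L)
    expect_equal(own$score, 50L)  # perfect self-hit found via a seed
  }
})

test_that("seed-and-extend equals the oracle wherever a seed exists", {
  # property over random small instances; eligibility = every transcript
  # the oracle scores above threshold has a seeded optimal diagonal,
  # established by an independent brute-force k-mer run scan
  n_checked <- 0L
  for (s in 1:25) {
    inst <- random_instance(s)
    scor <- scoring_scheme()
    asg <- align_all(inst$reads, inst$reference, scor, k = inst$k)
    orc <- oracle_assign(inst$reads, inst$reference, scor,
                         read_ids = names(inst$reads))
    oh <- oracle_align(inst$reads, inst$reference, scor)
    txseq <- setNames(inst$reference$transcripts$sequence,
                      inst$reference$transcripts$transcript_id)
    for (r in seq_along(inst$reads)) {
      h <- oh[oh$read == r, ]
      eligible <- nrow(h) == 0L ||
        all(vapply(seq_len(nrow(h)), function(j)
          has_seed_on_diagonal(inst$reads[[r]], txseq[[h$transcript_id[j]]],
                               h$start[j], inst$k), logical(1)))
      if (eligible) {
        n_checked <- n_checked + 1L
        expect_identical(asg[r, c("status", "gene_id")],
                         orc[r, c("status", "gene_id")])
      }
    }
  }
  expect_gt(n_checked, 200L)
})

test_that("the brute-force oracle matches an external ungapped aligner", {
  # cross-check the oracle itself against Biostrings with gaps forbidden
  fam <- tiny_family(n = 2, seed = 20)
  ref <- build_reference(fam)
  set.seed(30)
  rd <- substr(fam$sequences[["G01"]], 41, 100)
  ch <- strsplit(rd, "")[[1]]
  ch[c(10, 35)] <- c("A", "C")  # plant two substitutions (possibly no-ops)
  rd <- paste(ch, collapse = "")
  oh <- oracle_align(rd, ref, scoring_scheme(min_score_fraction = 0.1))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (j in seq_len(nrow(oh))) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = rd,
      subject = fam$sequences[[oh$gene_id[j]]],
      substitutionMatrix = mat, gapOpening = 1000, gapExtension = 1000,
      type = "global-local")
    expect_equal(oh$score[j], Biostrings::score(pa))
  }
})
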