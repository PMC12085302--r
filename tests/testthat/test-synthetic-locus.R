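test_that("exon plans validate their invariants", {
  p <- exon_plan(c(10, 20), c("a", "b"))
  expect_equal(plan_length(p), 30L)
  expect_equal(exon_ranges(p)$start, c(0L, 10L))
  expect_equal(exon_ranges(p)$end, c(10L, 30L))
  expect_error(exon_plan(c(10, 0)), "positive")
  expect_error(exon_plan(c(10, 20), c("a", "a")), "unique")
})

test_that("zero-divergence family reproduces the ancestor exactly", {
  fam <- generate_family(3, tiny_plan(), tiny_profile(1.0), seed = 7)
  expect_true(all(fam$sequences == fam$ancestor))
})

test_that("single-gene family and profile validation behave", {
  fam <- generate_family(1, tiny_plan(), tiny_profile(0.9), seed = 3)
  expect_equal(nrow(fam$genes), 1L)
  expect_error(generate_family(2, tiny_plan(), tiny_profile(1.2), seed = 1),
               "\\[0, 1\\]")
  expect_error(generate_family(2, tiny_plan(),
                               setNames(0.9, "1"), seed = 1),
               "missing exons")
})

test_that("families are byte-identical under a fixed seed", {
  f1 <- kir_preset_family(11)
  f2 <- kir_preset_family(11)
  expect_identical(f1$sequences, f2$sequences)
  f3 <- kir_preset_family(12)
  expect_false(identical(f1$sequences, f3$sequences))
})

test_that("realized identity tracks the profile within binomial tolerance", {
  # 0.95 target on a 300-nt exon; average realized identity over 20 seeds
  # recomputed with an independent position-wise comparison
  plan <- exon_plan(c(300L), "3")
  target <- 0.95
  ids <- vapply(1:20, function(s) {
    fam <- generate_family(2, plan, c(`3` = target), seed = s,
                           validate = FALSE)
    naive_identity(fam$sequences[[1]], fam$sequences[[2]])
  }, numeric(1))
  tol <- 3 * sqrt(target * (1 - target) / 300)
  expect_lt(abs(mean(ids) - target), tol)
})

test_that("lineage genes carry their exact per-exon substitution load", {
  lin <- data.frame(gene_id = "G02", parent = "G01", divergence = NA,
                    stringsAsFactors = FALSE)
  prof <- list(G02 = c(`1` = 0, `2` = 0.05, `3` = 0))
  fam <- generate_family(2, tiny_plan(), tiny_profile(0.95), seed = 5,
                         lineage = lin, lineage_profiles = prof,
                         validate = FALSE)
  d <- naive_diff(fam$sequences[["G01"]], fam$sequences[["G02"]])
  expect_equal(length(d), round(0.05 * 100))
  # all differences confined to exon 2 ([60, 160))
  expect_true(all(d >= 60 & d < 160))
})

test_that("alleles at zero divergence equal their gene reference", {
  fam <- tiny_family()
  al <- generate_alleles(fam, n_alleles_per_gene = 2,
                         allele_divergence = 0, seed = 1)
  expect_true(all(al$sequence ==
                    fam$sequences[al$gene_id]))
  expect_true(all(al$n_variants == 0L))
})

test_that("allele variant positions exactly describe the differences", {
  fam <- tiny_family()
  al <- generate_alleles(fam, n_alleles_per_gene = 3,
                         allele_divergence = 0.02, seed = 9)
  for (i in seq_len(nrow(al))) {
    expect_identical(al$variant_pos[[i]],
                     naive_diff(fam$sequences[[al$gene_id[i]]],
                                al$sequence[i]))
  }
  # expected load ~ d * L over the mutated alleles
  mut <- al[al$allele_name != "*001", ]
  expect_lt(abs(mean(mut$n_variants) - 0.02 * 220),
            3 * sqrt(0.02 * 0.98 * 220) / sqrt(nrow(mut)) + 1)
})

test_that("shared-exon override copies stated exons verbatim", {
  fam <- tiny_family()
  ov <- list(list(gene_id = "G01", allele_name = "*007",
                  from_gene = "G02", exons = c("1", "2")))
  al <- generate_alleles(fam, seed = 2, shared_exon_overrides = ov)
  a <- al$sequence[al$gene_id == "G01" & al$allele_name == "*007"]
  # identical to the donor gene over exons 1-2 ([0, 160))
  expect_equal(naive_identity(a, fam$sequences[["G02"]], 1, 160), 1.0)
  # still the host gene's sequence over exon 3
  expect_equal(naive_identity(a, fam$sequences[["G01"]], 161, 220), 1.0)
  bad <- list(list(gene_id = "G01", allele_name = "*008",
                   from_gene = "G02", exons = "9"))
  expect_error(generate_alleles(fam, seed = 2,
                                shared_exon_overrides = bad),
               "not in plan")
})

test_that("AA donors carry no B-associated gene; BB at p=1 carry all", {
  fam <- kir_preset_family(21)
  al <- generate_alleles(fam, seed = 1)
  b_genes <- fam$genes$gene_id[fam$genes$haplotype_assoc == "B_associated"]
  g_aa <- sample_genotype(fam, al, haplotype_model(pair = "AA"), seed = 1)
  expect_false(any(g_aa$presence[b_genes]))
  g_bb <- sample_genotype(fam, al,
                          haplotype_model(pair = "BB", b_presence = 1),
                          seed = 1)
  expect_true(all(g_bb$presence))
})

test_that("B-gene presence frequency matches the haplotype model", {
  fam <- kir_preset_family(22)
  al <- generate_alleles(fam, seed = 1)
  # one B haplotype, presence probability 0.5
  pres <- vapply(1:200, function(s)
    sample_genotype(fam, al, haplotype_model(pair = "AB", b_presence = 0.5),
                    seed = s)$presence[["KIR3DS1"]], logical(1))
  tol <- 3 * sqrt(0.5 * 0.5 / 200)
  expect_lt(abs(mean(pres) - 0.5), tol)
})

test_that("no genotype ever holds an allele of an absent gene", {
  fam <- tiny_family(n = 6)
  fam$genes$haplotype_assoc <- c("A_fixed", rep("B_associated", 5))
  al <- generate_alleles(fam, n_alleles_per_gene = 2, seed = 3)
  for (s in 1:1000) {
    g <- sample_genotype(fam, al, haplotype_model(), seed = s)
    absent <- names(g$presence)[!g$presence]
    expect_true(all(vapply(g$alleles[absent], is.null, logical(1))))
    present <- names(g$presence)[g$presence]
    expect_true(all(lengths(g$alleles[present]) %in% 1:2))
  }
})

test_that("family FASTA round trip preserves sequences and identities", {
  fam <- tiny_family(n = 4)
  fa <- tempfile(fileext = ".fa"); ann <- tempfile(fileext = ".tsv")
  write_family(fam, fa, ann)
  back <- load_family_from_fasta(fa, ann)
  expect_identical(back$sequences, fam$sequences)
  expect_identical(back$exon_plan$lengths, fam$exon_plan$lengths)
  expect_identical(back$genes$biotype, fam$genes$biotype)
  # per-exon identities survive the round trip
  expect_equal(exon_identity(back), exon_identity(fam),
               ignore_attr = TRUE)
  # annotation missing a record is an error
  a <- read.delim(ann, colClasses = c(exon = "character"))
  write.table(a[a$gene_id != "G02", ], ann, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(load_family_from_fasta(fa, ann), "missing")
})
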