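# shared fixtures and independent mini-oracles for the suite

tiny_plan <- function() exon_plan(c(60L, 100L, 60L), labels = c("1", "2", "3"))

tiny_profile <- function(id = 0.92) {
  setNames(rep(id, 3), c("1", "2", "3"))
}

tiny_family <- function(n = 4, seed = 42, id = 0.92, ...) {
  generate_family(n, tiny_plan(), tiny_profile(id), seed = seed, ...)
}

# independent position-wise identity (the brute-force oracle used to
# check exon_identity and the generator's realized divergence)
naive_identity <- function(a, b, from = 1L, to = nchar(a)) {
  av <- strsplit(a, "")[[1]][from:to]
  bv <- strsplit(b, "")[[1]][from:to]
  mean(av == bv)
}

# independent diff oracle (positions where two sequences disagree, 0-based)
naive_diff <- function(a, b) {
  which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]) - 1L
}

# random small alignment instance for oracle-equivalence checks:
# a small homologous family plus reads drawn from its transcripts
random_instance <- function(seed) {
  set.seed(seed)
  n_tx <- sample(2:8, 1)
  id <- runif(1, 0.85, 0.97)
  fam <- generate_family(n_tx, exon_plan(c(80L, 120L), c("1", "2")),
                         setNames(c(id, id), c("1", "2")),
                         seed = seed, validate = FALSE)
  ref <- build_reference(fam, name = "toy")
  n_reads <- sample(5:25, 1)
  L <- 50L
  err <- sample(c(0, 0.01, 0.02), 1)
  src <- sample(fam$genes$gene_id, n_reads, replace = TRUE)
  starts <- sample(0:(200L - L), n_reads, replace = TRUE)
  seqs <- vapply(seq_len(n_reads), function(i) {
    s <- substr(fam$sequences[[src[i]]], starts[i] + 1L, starts[i] + L)
    ne <- rbinom(1, L, err)
    if (ne > 0) {
      ch <- strsplit(s, "")[[1]]
      for (p in sample.int(L, ne))
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      s <- paste(ch, collapse = "")
    }
    s
  }, character(1))
  list(family = fam, reference = ref,
       reads = setNames(seqs, sprintf("t%03d", seq_len(n_reads))),
       true_gene = src, k = 11L)
}

# preset experiment shared across acceptance-style checks (computed once)
preset_result <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_experiment(kir_preset_config(seed = 1))
    cache
  }
})
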