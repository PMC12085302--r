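#' Simulate per-cell expression truth
#'
#' Each cell is positive for a present gene `g` with probability
#' `pos_freq(g)`; positive cells draw `1 + Poisson(mean - 1)` molecules.
#' Absent genes have zero molecules in every cell. Cell barcodes are
#' 16-nt and drawn without replacement (no collisions).
#'
#' @param genotype a `donor_genotype`.
#' @param n_cells number of cells (>= 0).
#' @param pos_freq scalar or named per-gene positive-cell frequency;
#'   names may only be present genes.
#' @param gene_mean scalar or named per-gene mean molecules per positive
#'   cell (>= 1).
#' @param seed integer seed.
#' @return Object of class `expression_truth`: `cells` (barcodes),
#'   `genes` (present genes), `counts` (data.frame `barcode`, `gene`,
#'   `molecules` for positive cells only) and `params`.
#' @export
simulate_expression <- function(genotype, n_cells, pos_freq = 0.25,
                                gene_mean = 3, seed) {
  stopifnot(inherits(genotype, "donor_genotype"))
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 0L) stopf("n_cells must be >= 0")
  present <- names(genotype$presence)[genotype$presence]
  for (par in list(pos_freq, gene_mean)) {
    if (!is.null(names(par))) {
      absent <- setdiff(names(par), present)
      if (length(absent))
        stopf("parameters given for absent gene(s): %s",
              paste(absent, collapse = ", "))
    }
  }
  par_of <- function(par, g, default) {
    if (is.null(names(par))) return(par[[1L]])
    if (g %in% names(par)) par[[g]] else default
  }
  set.seed(as.integer(seed))
  barcodes <- if (n_cells) int_to_dna(sample(4^16, n_cells), 16L) else character(0)

  rows <- list()
  for (g in present) {
    p <- par_of(pos_freq, g, 0.25)
    mu <- par_of(gene_mean, g, 3)
    if (mu < 1) stopf("gene_mean must be >= 1 (gene %s)", g)
    pos <- which(runif(n_cells) < p)
    if (!length(pos)) next
    mol <- 1L + rpois(length(pos), mu - 1)
    rows[[g]] <- data.frame(barcode = barcodes[pos], gene = g,
                            molecules = as.integer(mol),
                            stringsAsFactors = FALSE)
  }
  counts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(barcode = character(0), gene = character(0),
               molecules = integer(0), stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  structure(list(cells = barcodes, genes = present, counts = counts,
                 params = list(n_cells = n_cells, pos_freq = pos_freq,
                               gene_mean = gene_mean, seed = seed)),
            class = "expression_truth")
}

## start-position weights over valid offsets 0..max_start
start_weights <- function(start_model, max_start) {
  offs <- 0:max_start
  if (identical(start_model$type, "uniform")) {
    rep(1 / (max_start + 1), max_start + 1L)
  } else {  # truncated geometric 5' window
    p <- start_model$p %||% 0.05
    w <- (1 - p)^offs * p
    w / sum(w)
  }
}

#' Simulate 5'-tag reads from an expression truth
#'
#' Every molecule gets a globally unique 10-nt UMI and
#' `reads_per_molecule` reads sharing its cell barcode and UMI. Each
#' read's start offset on the source allele is drawn from `start_model`
#' (default: truncated geometric with `p = 0.05` from the 5' end, the
#' 10x 5'-chemistry stressing case; `list(type = "uniform")` for a flat
#' start). Substitution errors are i.i.d. per base at `error_rate`; the
#' realized error count is recorded. A molecule's allele is drawn
#' uniformly from the donor's alleles for its gene.
#'
#' @param truth an `expression_truth`.
#' @param genotype the `donor_genotype` the truth was simulated from.
#' @param alleles the `allele_set` providing allele sequences.
#' @param read_length read length (<= transcript length).
#' @param error_rate per-base substitution probability in `[0, 1)`.
#' @param reads_per_molecule duplicate reads per molecule (>= 1).
#' @param start_model list with `type` (`"geometric"` or `"uniform"`)
#'   and, for geometric, `p`.
#' @param seed integer seed.
#' @return data.frame of class `sim_reads`: `read_id`
#'   (`"r<n>:<barcode>:<umi>"`), `barcode`, `umi`, `sequence`,
#'   `true_gene`, `true_allele`, `true_start` (0-based), `n_errors`.
#' @export
simulate_reads <- function(truth, genotype, alleles, read_length = 90L,
                           error_rate = 0, reads_per_molecule = 1L,
                           start_model = list(type = "geometric", p = 0.05),
                           seed) {
  stopifnot(inherits(truth, "expression_truth"),
            inherits(genotype, "donor_genotype"))
  if (error_rate < 0 || error_rate >= 1) stopf("error_rate must be in [0, 1)")
  read_length <- as.integer(read_length)
  reads_per_molecule <- max(1L, as.integer(reads_per_molecule))

  allele_seq <- setNames(alleles$sequence,
                         paste0(alleles$gene_id, alleles$allele_name))
  tx_len <- unique(nchar(alleles$sequence))
  if (length(tx_len) != 1L)
    stopf("allele sequences must share one length")
  if (read_length > tx_len)
    stopf("read_length %d exceeds transcript length %d", read_length, tx_len)

  set.seed(as.integer(seed))
  empty <- data.frame(read_id = character(0), barcode = character(0),
                      umi = character(0), sequence = character(0),
                      true_gene = character(0), true_allele = character(0),
                      true_start = integer(0), n_errors = integer(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("sim_reads", "data.frame")
  if (!nrow(truth$counts)) return(empty)

  ## molecule table: one row per molecule
  mol <- truth$counts[rep(seq_len(nrow(truth$counts)),
                          truth$counts$molecules), c("barcode", "gene")]
  n_mol <- nrow(mol)
  bad <- setdiff(unique(mol$gene), names(genotype$presence)[genotype$presence])
  if (length(bad))
    stopf("truth contains molecules of absent gene(s): %s",
          paste(bad, collapse = ", "))
  mol$allele <- vapply(mol$gene, function(g) {
    a <- genotype$alleles[[g]]
    if (length(a) > 1L) sample(a, 1L) else a
  }, character(1L), USE.NAMES = FALSE)
  mol$umi <- int_to_dna(sample(4^10, n_mol), 10L)

  ## expand to reads
  n_reads <- n_mol * reads_per_molecule
  idx <- rep(seq_len(n_mol), each = reads_per_molecule)
  w <- start_weights(start_model, tx_len - read_length)
  starts <- sample.int(length(w), n_reads, replace = TRUE, prob = w) - 1L
  key <- paste0(mol$gene[idx], mol$allele[idx])
  seqs <- substring(allele_seq[key], starts + 1L, starts + read_length)

  n_err <- rbinom(n_reads, read_length, error_rate)
  if (any(n_err > 0L)) {
    for (i in which(n_err > 0L)) {
      ch <- seq_chars(seqs[i])
      ch <- mutate_positions(ch, sample.int(read_length, n_err[i]))
      seqs[i] <- paste(ch, collapse = "")
    }
  }

  out <- data.frame(
    read_id = sprintf("r%07d:%s:%s", seq_len(n_reads),
                      mol$barcode[idx], mol$umi[idx]),
    barcode = mol$barcode[idx], umi = mol$umi[idx],
    sequence = unname(seqs),
    true_gene = mol$gene[idx], true_allele = mol$allele[idx],
    true_start = starts, n_errors = n_err,
    stringsAsFactors = FALSE)
  class(out) <- c("sim_reads", "data.frame")
  out
}

#' FASTQ and truth-table writers / readers
#'
#' Reads are written as single-end cDNA FASTQ; the cell barcode and UMI
#' travel in the read name (`r<n>:<barcode>:<umi>`), so the FASTQ is
#' lossless without an index file. All base qualities are Q37. The truth
#' table is a TSV joinable to the FASTQ on `read_id`.
#'
#' @param reads a `sim_reads` data.frame.
#' @param path output/input file path.
#' @return `read_fastq_reads()`: data.frame with `read_id`, `barcode`,
#'   `umi`, `sequence`.
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  q <- Biostrings::BStringSet(strrep("F", nchar(reads$sequence)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname write_reads_fastq
#' @export
write_truth_table <- function(reads, path) {
  write.table(reads[, c("read_id", "barcode", "umi", "true_gene",
                        "true_allele", "true_start", "n_errors")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reads_fastq
#' @export
read_fastq_reads <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  ids <- names(x)
  parts <- strsplit(ids, ":", fixed = TRUE)
  bad <- ids[lengths(parts) != 3L]
  if (length(bad))
    stopf("read name not in r<n>:<barcode>:<umi> form: %s", bad[1L])
  data.frame(read_id = ids,
             barcode = vapply(parts, `[[`, character(1), 2L),
             umi = vapply(parts, `[[`, character(1), 3L),
             sequence = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname write_reads_fastq
#' @export
read_truth_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
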