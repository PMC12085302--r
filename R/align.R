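#' Scoring scheme for the ungapped mapper
#'
#' @param match match reward (> 0).
#' @param mismatch mismatch penalty (<= 0).
#' @param min_score_fraction fraction of the perfect score
#'   (`match * read_length`) a hit must reach to be reported, in
#'   `(0, 1]`. The acceptance floor is what sends reads of a
#'   sufficiently diverged gene to "unmapped" instead of a homolog.
#' @return list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -1L,
                           min_score_fraction = 0.8) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  if (!(match > 0L) || mismatch > 0L)
    stopf("need match > 0 and mismatch <= 0")
  if (min_score_fraction <= 0 || min_score_fraction > 1)
    stopf("min_score_fraction must lie in (0, 1]")
  structure(list(match = match, mismatch = mismatch,
                 min_score_fraction = min_score_fraction),
            class = "scoring_scheme")
}

#' Build a k-mer index over a reference
#'
#' Exact, complete postings: every k-mer occurrence of every transcript
#' is indexed (`sum(max(0, len - k + 1))` postings in total).
#'
#' @param reference a `reference_set`.
#' @param k k-mer length (>= 8).
#' @return list of class `kmer_index` (`k`, `transcript_id`, `gene_id`,
#'   `n_postings` and an external pointer to the postings map). Use
#'   [kmer_postings()] to materialize postings for inspection.
#' @export
build_kmer_index <- function(reference, k = 21L) {
  stopifnot(inherits(reference, "reference_set"))
  k <- as.integer(k)
  if (k < 8L) stopf("k must be >= 8")
  tx <- reference$transcripts
  if (k > max(nchar(tx$sequence)))
    warnf("k exceeds the longest transcript; index is empty")
  ptr <- cpp_build_index(tx$sequence, tx$transcript_id, tx$gene_id, k)
  structure(list(ptr = ptr, k = k,
                 reference_name = reference$name,
                 transcript_id = tx$transcript_id,
                 gene_id = tx$gene_id,
                 n_postings = cpp_index_n_postings(ptr)),
            class = "kmer_index")
}

#' @rdname build_kmer_index
#' @param index a `kmer_index`.
#' @return `kmer_postings()`: data.frame `kmer`, `transcript_id`,
#'   `offset` (0-based).
#' @export
kmer_postings <- function(index) {
  stopifnot(inherits(index, "kmer_index"))
  cpp_index_postings(index$ptr)
}

## shared hit post-processing: cpp hit table -> labelled data.frame
hits_frame <- function(raw, index) {
  data.frame(read = raw$read,
             transcript_id = index$transcript_id[raw$tx],
             gene_id = index$gene_id[raw$tx],
             start = raw$start, score = raw$score,
             n_mismatches = raw$n_mismatches,
             stringsAsFactors = FALSE)
}

#' Align one read
#'
#' Seed-and-extend: exact k-mer seeds propose (transcript, diagonal)
#' candidates; each candidate is scored by ungapped extension over the
#' full read; the best hit per transcript at or above the acceptance
#' threshold is reported. A read shorter than `k` has no seeds and
#' yields no hits.
#'
#' @param read_seq read sequence (character scalar).
#' @param index a `kmer_index`.
#' @param scoring a [scoring_scheme()].
#' @return data.frame of hits: `transcript_id`, `gene_id`, `start`
#'   (0-based), `score`, `n_mismatches`.
#' @export
align_read <- function(read_seq, index, scoring = scoring_scheme()) {
  stopifnot(inherits(index, "kmer_index"), is.character(read_seq),
            length(read_seq) == 1L)
  raw <- cpp_align(index$ptr, read_seq, scoring$match, scoring$mismatch,
                   scoring$min_score_fraction)
  hits_frame(raw, index)[, -1L]
}

#' Assign a read from its hits
#'
#' No hits: `unmapped`. Top score achieved (within `tie_margin`) by
#' transcripts of a single gene (a donor's two alleles count as one
#' gene): `unique` to that gene. Top score achieved on two or more
#' genes: `multimapped` — ties are never broken; they are the
#' multi-mapping signal itself. `margin` is the gap between the best
#' gene and the runner-up gene (NA when only one gene has hits).
#'
#' @param hits data.frame from [align_read()].
#' @param tie_margin score margin within which genes count as tied
#'   (default 0 = exact ties).
#' @return one-row data.frame: `status`, `gene_id`, `best_score`,
#'   `margin`.
#' @export
assign_read <- function(hits, tie_margin = 0) {
  if (is.null(hits) || !nrow(hits)) {
    return(data.frame(status = "unmapped", gene_id = NA_character_,
                      best_score = NA_integer_, margin = NA_real_,
                      stringsAsFactors = FALSE))
  }
  gene_best <- tapply(hits$score, hits$gene_id, max)
  top <- max(gene_best)
  tied <- names(gene_best)[gene_best >= top - tie_margin]
  margin <- if (length(gene_best) > 1L)
    top - max(gene_best[names(gene_best) != tied[1L]]) else NA_real_
  if (length(tied) == 1L) {
    data.frame(status = "unique", gene_id = tied, best_score = top,
               margin = margin, stringsAsFactors = FALSE)
  } else {
    data.frame(status = "multimapped", gene_id = NA_character_,
               best_score = top, margin = margin, stringsAsFactors = FALSE)
  }
}

## vectorized assignment over a many-read hit table (data.table);
## returns one row per read index in `read_ids` order
assign_hits_table <- function(hits, read_ids, tie_margin = 0) {
  n <- length(read_ids)
  out <- data.table::data.table(
    read_id = read_ids, status = "unmapped", gene_id = NA_character_,
    best_score = NA_integer_, margin = NA_real_,
    transcript_id = NA_character_, start = NA_integer_,
    n_mismatches = NA_integer_)
  if (nrow(hits)) {
    h <- data.table::as.data.table(hits)
    gb <- h[, .(gscore = max(score)), by = .(read, gene_id)]
    data.table::setorder(gb, read, -gscore)
    smry <- gb[, {
      top <- gscore[1L]
      tied <- sum(gscore >= top - tie_margin)
      .(top = top, tied = tied,
        gene = if (tied == 1L) gene_id[1L] else NA_character_,
        margin = if (.N > 1L) as.numeric(top - gscore[2L]) else NA_real_)
    }, by = read]
    ## best hit detail for uniquely assigned reads
    uq <- smry[tied == 1L]
    if (nrow(uq)) {
      hb <- h[uq, on = c(read = "read", gene_id = "gene", score = "top")]
      hb <- hb[!duplicated(read)]
      out[hb$read, `:=`(transcript_id = hb$transcript_id,
                        start = hb$start, n_mismatches = hb$n_mismatches)]
    }
    out[smry$read, `:=`(
      status = ifelse(smry$tied == 1L, "unique", "multimapped"),
      gene_id = smry$gene, best_score = as.integer(smry$top),
      margin = smry$margin)]
  }
  as.data.frame(out)
}

#' Align and assign a full read set
#'
#' One assignment record per input read; `unique + multimapped +
#' unmapped` always equals the number of reads.
#'
#' @param reads a `sim_reads` data.frame, a FASTQ path, or a named
#'   character vector of sequences.
#' @param reference a `reference_set`.
#' @param scoring a [scoring_scheme()].
#' @param k k-mer length.
#' @param tie_margin see [assign_read()].
#' @param index optional prebuilt `kmer_index` (must match `reference`).
#' @return data.frame of class `assignment_table`: `read_id`, `status`
#'   (`unique` / `multimapped` / `unmapped`), `gene_id` (NA unless
#'   unique), `best_score`, `margin`, `transcript_id`, `start`,
#'   `n_mismatches` (best-hit detail, NA unless unique). Status counts
#'   are in the `status_counts` attribute.
#' @export
align_all <- function(reads, reference, scoring = scoring_scheme(),
                      k = 21L, tie_margin = 0, index = NULL) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq_reads(reads)
  if (is.data.frame(reads)) {
    if (!all(c("read_id", "sequence") %in% names(reads)))
      stopf("reads data.frame needs read_id and sequence columns")
    ids <- reads$read_id; seqs <- reads$sequence
  } else {
    seqs <- unname(reads)
    ids <- names(reads) %||% sprintf("r%07d", seq_along(seqs))
  }
  if (is.null(index)) index <- build_kmer_index(reference, k)
  raw <- cpp_align(index$ptr, seqs, scoring$match, scoring$mismatch,
                   scoring$min_score_fraction)
  out <- assign_hits_table(hits_frame(raw, index), ids, tie_margin)
  attr(out, "status_counts") <- table(factor(
    out$status, levels = c("unique", "multimapped", "unmapped")))
  attr(out, "reference") <- reference$name
  class(out) <- c("assignment_table", "data.frame")
  out
}
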