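#' Write / read a reference as FASTA + GTF
#'
#' Transcript sequences go to FASTA; the annotation goes to a standard
#' GTF with one `exon` feature per transcript exon, `gene_id`,
#' `transcript_id`, `gene_biotype` and `exon_id` attributes, and the
#' transcript itself as the sequence. Internal coordinates are 0-based,
#' half-open; GTF is written 1-based, inclusive (an internal span
#' `[0, 100)` serializes as `1..100`).
#'
#' @param reference a `reference_set`.
#' @param fasta_path,gtf_path file paths.
#' @return `write_reference()`: invisibly, the GTF path.
#' @export
write_reference <- function(reference, fasta_path, gtf_path) {
  stopifnot(inherits(reference, "reference_set"))
  tx <- reference$transcripts
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(tx$sequence, tx$transcript_id)),
    fasta_path)
  rng <- exon_ranges(reference$exon_plan)
  n_ex <- nrow(rng)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(tx$transcript_id, each = n_ex),
    ranges = IRanges::IRanges(start = rep(rng$start + 1L, nrow(tx)),
                              end = rep(rng$end, nrow(tx))),
    strand = "+")
  S4Vectors::mcols(gr)$source <- "kirsim"
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$gene_id <- rep(tx$gene_id, each = n_ex)
  S4Vectors::mcols(gr)$transcript_id <- rep(tx$transcript_id, each = n_ex)
  S4Vectors::mcols(gr)$gene_biotype <- rep(tx$biotype, each = n_ex)
  S4Vectors::mcols(gr)$exon_id <- rep(rng$exon, nrow(tx))
  rtracklayer::export(gr, gtf_path, format = "gtf")
  invisible(gtf_path)
}

#' @rdname write_reference
#' @param name,mode metadata for the rebuilt `reference_set`.
#' @export
read_reference <- function(fasta_path, gtf_path, name = "reference",
                           mode = "custom") {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  md <- as.data.frame(gr)
  if (!all(c("gene_id", "transcript_id", "gene_biotype") %in% names(md)))
    stopf("GTF lacks gene_id/transcript_id/gene_biotype attributes")

  ## exon plan from the first transcript's rows (1-based inclusive -> plan)
  t1 <- md[md$transcript_id == md$transcript_id[1L], ]
  t1 <- t1[order(t1$start), ]
  plan <- exon_plan(t1$end - t1$start + 1L,
                    labels = if ("exon_id" %in% names(t1)) t1$exon_id
                             else as.character(seq_len(nrow(t1))))

  u <- unique(md[, c("transcript_id", "gene_id", "gene_biotype")])
  u <- u[match(names(seqs), u$transcript_id), ]
  if (any(is.na(u$gene_id)))
    stopf("GTF missing transcript(s) present in FASTA")
  tx <- data.frame(transcript_id = u$transcript_id, gene_id = u$gene_id,
                   biotype = u$gene_biotype,
                   sequence = as.character(seqs), stringsAsFactors = FALSE)
  rownames(tx) <- NULL
  if (any(nchar(tx$sequence) != plan_length(plan)))
    stopf("FASTA sequence length disagrees with GTF exon spans")
  structure(list(name = name, mode = mode, transcripts = tx,
                 exon_plan = plan, filter_applied = FALSE,
                 allowed_biotypes = NULL),
            class = "reference_set")
}
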