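#' Write a gene family to FASTA + annotation TSV
#'
#' FASTA records are the gene reference sequences (one per gene, named by
#' `gene_id`). The annotation table has one row per gene and exon with
#' columns `gene_id`, `biotype`, `receptor_class`, `haplotype_assoc`,
#' `exon`, `start`, `end` (0-based, half-open transcript offsets).
#'
#' @param family a `gene_family`.
#' @param fasta_path,annotation_path output paths.
#' @return invisibly, the annotation data.frame.
#' @export
write_family <- function(family, fasta_path, annotation_path) {
  stopifnot(inherits(family, "gene_family"))
  seqs <- Biostrings::DNAStringSet(family$sequences)
  Biostrings::writeXStringSet(seqs, fasta_path)
  rng <- exon_ranges(family$exon_plan)
  ann <- merge(family$genes, rng, by = NULL)  # cartesian gene x exon
  ann <- ann[order(match(ann$gene_id, family$genes$gene_id), ann$start),
             c("gene_id", "biotype", "receptor_class", "haplotype_assoc",
               "exon", "start", "end")]
  write.table(ann, annotation_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(ann)
}

#' Load a gene family from FASTA + annotation TSV
#'
#' Inverse of [write_family()]; also the entry point for real,
#' pre-aligned KIR sequences (equal-length records sharing one exon
#' plan). Sequences are used unmodified. The ancestor sequence and
#' generation seed of a loaded family are unknown (`NA`).
#'
#' @param fasta_path,annotation_path input paths.
#' @return A `gene_family`.
#' @export
load_family_from_fasta <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- names(seqs)
  if (anyDuplicated(ids)) stopf("duplicate FASTA record ids")
  ann <- read.delim(annotation_path, stringsAsFactors = FALSE,
                    colClasses = c(exon = "character"))
  need <- c("gene_id", "biotype", "receptor_class", "haplotype_assoc",
            "exon", "start", "end")
  if (!all(need %in% names(ann)))
    stopf("annotation must have columns %s", paste(need, collapse = ", "))
  missing_ann <- setdiff(ids, ann$gene_id)
  if (length(missing_ann))
    stopf("annotation missing record(s): %s", paste(missing_ann, collapse = ", "))

  ## rebuild the exon plan from the first gene's rows
  a1 <- ann[ann$gene_id == ids[1L], ]
  a1 <- a1[order(a1$start), ]
  plan <- exon_plan(a1$end - a1$start, labels = a1$exon)
  L <- plan_length(plan)
  bad <- ids[Biostrings::width(seqs) != L]
  if (length(bad))
    stopf("record length != exon-span total for: %s", paste(bad, collapse = ", "))

  meta <- unique(ann[, c("gene_id", "biotype", "receptor_class",
                         "haplotype_assoc")])
  meta <- meta[match(ids, meta$gene_id), ]
  rownames(meta) <- NULL
  structure(list(genes = meta,
                 sequences = setNames(as.character(seqs), ids),
                 exon_plan = plan,
                 ancestor = NA_character_,
                 identity_profile = NULL,
                 lineage = NULL,
                 seed = NA_integer_),
            class = "gene_family")
}
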