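#' Build a transcript reference from a gene family
#'
#' Assembles the transcript set an aligner would be given. By default one
#' transcript per gene (the gene reference sequence); with
#' `allele_policy = "named_allele_per_gene"` the stated allele replaces
#' the reference sequence; with `allele_policy = "donor_alleles"` a
#' genotype's alleles are used, either collapsed to one transcript per
#' gene (first allele) or expanded to one transcript per allele
#' (`one_transcript_per_allele = TRUE`) — allele transcripts share their
#' `gene_id`, so gene-level assignment is unaffected.
#'
#' @param family a `gene_family`.
#' @param gene_subset character vector of gene ids to include (non-empty).
#' @param allele_policy `"reference_allele"` (default),
#'   `"named_allele_per_gene"` or `"donor_alleles"`.
#' @param name reference name.
#' @param mode `"restricted"`, `"full"` or `"custom"`.
#' @param alleles an `allele_set` (required for non-default policies).
#' @param named_alleles named character vector `gene_id -> allele_name`
#'   for `"named_allele_per_gene"`.
#' @param genotype a `donor_genotype` for `"donor_alleles"`.
#' @param one_transcript_per_allele include every donor allele as its own
#'   transcript.
#' @return An object of class `reference_set`: `name`, `mode`,
#'   `transcripts` (data.frame `transcript_id`, `gene_id`, `biotype`,
#'   `sequence`), `exon_plan`, `filter_applied`, `allowed_biotypes`.
#' @export
build_reference <- function(family, gene_subset = NULL,
                            allele_policy = c("reference_allele",
                                              "named_allele_per_gene",
                                              "donor_alleles"),
                            name = "reference", mode = "custom",
                            alleles = NULL, named_alleles = NULL,
                            genotype = NULL,
                            one_transcript_per_allele = FALSE) {
  stopifnot(inherits(family, "gene_family"))
  allele_policy <- match.arg(allele_policy)
  mode <- match.arg(mode, c("restricted", "full", "custom"))
  gene_subset <- gene_subset %||% family$genes$gene_id
  if (!length(gene_subset)) stopf("gene_subset must be non-empty")
  unknown <- setdiff(gene_subset, family$genes$gene_id)
  if (length(unknown))
    stopf("gene_subset names unknown genes: %s", paste(unknown, collapse = ", "))

  meta <- family$genes[match(gene_subset, family$genes$gene_id), ]
  tx <- list()
  for (i in seq_along(gene_subset)) {
    g <- gene_subset[i]
    if (allele_policy == "reference_allele") {
      tx[[length(tx) + 1L]] <- data.frame(
        transcript_id = g, gene_id = g, biotype = meta$biotype[i],
        sequence = family$sequences[[g]], stringsAsFactors = FALSE)
    } else if (allele_policy == "named_allele_per_gene") {
      if (is.null(alleles) || is.null(named_alleles))
        stopf("named_allele_per_gene needs alleles and named_alleles")
      an <- named_alleles[[g]] %||% "*001"
      row <- alleles[alleles$gene_id == g & alleles$allele_name == an, ]
      if (!nrow(row)) stopf("allele %s%s not found", g, an)
      tx[[length(tx) + 1L]] <- data.frame(
        transcript_id = paste0(g, an), gene_id = g, biotype = meta$biotype[i],
        sequence = row$sequence, stringsAsFactors = FALSE)
    } else {
      if (is.null(alleles) || is.null(genotype))
        stopf("donor_alleles needs alleles and a genotype")
      ans <- genotype$alleles[[g]]
      if (is.null(ans)) next  # absent gene: no transcript
      if (!one_transcript_per_allele) ans <- ans[1L]
      for (an in ans) {
        row <- alleles[alleles$gene_id == g & alleles$allele_name == an, ]
        if (!nrow(row)) stopf("allele %s%s not found", g, an)
        tx[[length(tx) + 1L]] <- data.frame(
          transcript_id = paste0(g, an), gene_id = g,
          biotype = meta$biotype[i], sequence = row$sequence,
          stringsAsFactors = FALSE)
      }
    }
  }
  tx <- do.call(rbind, tx)
  if (is.null(tx) || !nrow(tx)) stopf("reference has no transcripts")
  if (anyDuplicated(tx$transcript_id)) stopf("duplicate transcript ids")
  rownames(tx) <- NULL
  structure(list(name = name, mode = mode, transcripts = tx,
                 exon_plan = family$exon_plan,
                 filter_applied = FALSE, allowed_biotypes = NULL),
            class = "reference_set")
}

#' Restricted (GRCh38-like) and full (all-KIR) reference presets
#'
#' `restricted_reference()` keeps the genes flagged `in_grch38` in
#' [kir_fixture()] that exist in the family (7 genes for the KIR preset);
#' `full_reference()` keeps every gene (16 entries: 14 functional genes
#' plus 2 pseudogenes for the KIR preset).
#'
#' @param family a `gene_family`.
#' @param ... passed to [build_reference()].
#' @return A `reference_set`.
#' @export
restricted_reference <- function(family, ...) {
  fx <- kir_fixture("merged")
  keep <- intersect(fx$gene_id[fx$in_grch38], family$genes$gene_id)
  if (!length(keep))
    stopf("family shares no genes with the GRCh38 KIR content")
  build_reference(family, gene_subset = keep, name = "restricted",
                  mode = "restricted", ...)
}

#' @rdname restricted_reference
#' @export
full_reference <- function(family, ...) {
  build_reference(family, gene_subset = family$genes$gene_id,
                  name = "full", mode = "full", ...)
}

#' Apply a biotype annotation filter
#'
#' Models the default single-cell pipeline's filtered gene annotation:
#' transcripts whose biotype is not in `allowed_biotypes` are removed
#' from the countable reference (a `polymorphic_pseudogene` such as
#' KIR2DS4 is silently dropped by the default `"functional"` allow-list
#' even though its sequence is in the assembly). Removals are recorded in
#' the `removed` attribute with the offending biotype as the reason.
#' Downstream counting only quantifies surviving genes.
#'
#' @param reference a `reference_set`.
#' @param allowed_biotypes non-empty character vector of biotypes to keep
#'   (default `"functional"`).
#' @return The filtered `reference_set` (possibly empty, with a warning).
#' @export
filter_annotation <- function(reference, allowed_biotypes = "functional") {
  stopifnot(inherits(reference, "reference_set"))
  if (!length(allowed_biotypes)) stopf("allowed_biotypes must be non-empty")
  keep <- reference$transcripts$biotype %in% allowed_biotypes
  removed <- unique(reference$transcripts[!keep, c("gene_id", "biotype")])
  if (nrow(removed)) removed$reason <-
      sprintf("biotype '%s' not in allow-list", removed$biotype)
  out <- reference
  out$transcripts <- reference$transcripts[keep, , drop = FALSE]
  rownames(out$transcripts) <- NULL
  out$filter_applied <- TRUE
  out$allowed_biotypes <- allowed_biotypes
  attr(out, "removed") <- removed
  if (!nrow(out$transcripts))
    warnf("annotation filter removed every transcript")
  out
}

#' Genes of a reference
#' @param reference a `reference_set`.
#' @return character vector of unique gene ids.
#' @export
reference_genes <- function(reference) {
  stopifnot(inherits(reference, "reference_set"))
  unique(reference$transcripts$gene_id)
}

#' @export
print.reference_set <- function(x, ...) {
  cat("reference_set '", x$name, "' (", x$mode, "): ",
      nrow(x$transcripts), " transcripts, ",
      length(unique(x$transcripts$gene_id)), " genes",
      if (x$filter_applied) " [biotype-filtered]" else "", "\n", sep = "")
  invisible(x)
}
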