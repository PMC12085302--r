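#' Generate allele sets for a gene family
#'
#' Every gene receives a reference allele `*001` (identical to the gene
#' sequence) plus `n_alleles_per_gene - 1` alleles mutated from it at a
#' flat per-site rate. `variant_positions` are recomputed from the final
#' sequence, so they exactly describe the differences from the gene
#' reference.
#'
#' A `shared_exon_overrides` entry copies stated exons verbatim from
#' another gene's reference sequence into an allele — the construction
#' used to reproduce allele-dependent locus confusion (an allele of one
#' gene identical to another gene's reference over its 5' exons).
#'
#' @param family a `gene_family`.
#' @param n_alleles_per_gene alleles per gene (>= 1).
#' @param allele_divergence per-site substitution rate for non-reference
#'   alleles, in `[0, 1)`.
#' @param seed integer seed.
#' @param shared_exon_overrides optional list of lists with fields
#'   `gene_id`, `allele_name`, `from_gene`, `exons` (character labels):
#'   adds an allele of `gene_id` whose stated exons are copied from
#'   `from_gene`.
#' @return data.frame of class `allele_set`: `gene_id`, `allele_name`,
#'   `sequence`, `n_variants`, plus list-columns `variant_pos` (0-based
#'   transcript offsets) and `variant_base`.
#' @export
generate_alleles <- function(family, n_alleles_per_gene = 1L,
                             allele_divergence = 0.002, seed,
                             shared_exon_overrides = NULL) {
  stopifnot(inherits(family, "gene_family"))
  if (allele_divergence < 0 || allele_divergence >= 1)
    stopf("allele_divergence must lie in [0, 1)")
  n_alleles_per_gene <- max(1L, as.integer(n_alleles_per_gene))
  set.seed(as.integer(seed))
  L <- plan_length(family$exon_plan)
  rng <- exon_ranges(family$exon_plan)

  rows <- list()
  for (g in family$genes$gene_id) {
    ref <- family$sequences[[g]]
    for (a in seq_len(n_alleles_per_gene)) {
      nm <- sprintf("*%03d", a)
      if (a == 1L || allele_divergence == 0) {
        seq <- ref
      } else {
        chars <- seq_chars(ref)
        nmut <- rbinom(1L, L, allele_divergence)
        if (nmut > 0L) chars <- mutate_positions(chars, sample.int(L, nmut))
        seq <- paste(chars, collapse = "")
      }
      rows[[length(rows) + 1L]] <- list(gene_id = g, allele_name = nm,
                                        sequence = seq)
    }
  }

  for (ov in shared_exon_overrides %||% list()) {
    need <- c("gene_id", "allele_name", "from_gene", "exons")
    if (!all(need %in% names(ov)))
      stopf("shared-exon override needs fields %s", paste(need, collapse = ", "))
    if (!all(ov$exons %in% family$exon_plan$labels))
      stopf("override exon label(s) not in plan: %s",
            paste(setdiff(ov$exons, family$exon_plan$labels), collapse = ", "))
    if (!ov$from_gene %in% names(family$sequences))
      stopf("override from_gene %s not in family", ov$from_gene)
    chars <- seq_chars(family$sequences[[ov$gene_id]])
    donor <- seq_chars(family$sequences[[ov$from_gene]])
    for (ex in ov$exons) {
      i <- which(rng$exon == ex)
      span <- (rng$start[i] + 1L):rng$end[i]
      chars[span] <- donor[span]
    }
    rows[[length(rows) + 1L]] <- list(gene_id = ov$gene_id,
                                      allele_name = ov$allele_name,
                                      sequence = paste(chars, collapse = ""))
  }

  out <- data.frame(
    gene_id = vapply(rows, `[[`, character(1), "gene_id"),
    allele_name = vapply(rows, `[[`, character(1), "allele_name"),
    sequence = vapply(rows, `[[`, character(1), "sequence"),
    stringsAsFactors = FALSE)
  if (anyDuplicated(paste(out$gene_id, out$allele_name)))
    stopf("duplicate (gene_id, allele_name) pair")

  ## recompute variant positions vs the gene reference (exact by design)
  vp <- vector("list", nrow(out)); vb <- vector("list", nrow(out))
  for (i in seq_len(nrow(out))) {
    ref <- seq_chars(family$sequences[[out$gene_id[i]]])
    alt <- seq_chars(out$sequence[i])
    d <- which(ref != alt)
    vp[[i]] <- d - 1L            # 0-based offsets
    vb[[i]] <- alt[d]
  }
  out$n_variants <- lengths(vp)
  out$variant_pos <- vp
  out$variant_base <- vb
  class(out) <- c("allele_set", "data.frame")
  out
}
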