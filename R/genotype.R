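#' Haplotype model for donor genotype sampling
#'
#' The KIR complex segregates into A haplotypes (fixed, largely
#' inhibitory gene content) and B haplotypes (variable content including
#' activating genes). Under this model, `A_fixed` and `framework` genes
#' are always present; `B_associated` genes can be carried only by a B
#' haplotype, each with a stated presence probability per B haplotype.
#'
#' @param pair one of `"AA"`, `"AB"`, `"BB"`, or `NULL` to sample from
#'   `pair_probs`.
#' @param pair_probs named probabilities for `AA`/`AB`/`BB` (used when
#'   `pair` is `NULL`).
#' @param b_presence scalar or per-gene named probability that a
#'   B-associated gene is carried by one B haplotype.
#' @return list of class `haplotype_model`.
#' @export
haplotype_model <- function(pair = NULL,
                            pair_probs = c(AA = 0.25, AB = 0.5, BB = 0.25),
                            b_presence = 0.5) {
  if (!is.null(pair)) pair <- match.arg(pair, c("AA", "AB", "BB"))
  structure(list(pair = pair, pair_probs = pair_probs,
                 b_presence = b_presence),
            class = "haplotype_model")
}

#' Sample a donor genotype
#'
#' Draws a haplotype pair, per-gene presence and an allele pair per
#' present gene. All `A_fixed` and `framework` genes are present
#' regardless of haplotype pair; a `B_associated` gene is present with
#' probability `1 - (1 - p)^nB` where `nB` is the number of B haplotypes.
#' Present genes draw two alleles with replacement from the gene's allele
#' list (homozygous draws collapse to one allele); absent genes carry
#' none.
#'
#' @param family a `gene_family`.
#' @param alleles an `allele_set` from [generate_alleles()].
#' @param model a [haplotype_model()].
#' @param seed integer seed.
#' @param donor_id donor label.
#' @return list of class `donor_genotype`: `donor_id`, `pair`,
#'   `presence` (named logical) and `alleles` (named list of allele-name
#'   vectors, length 1-2 for present genes).
#' @export
sample_genotype <- function(family, alleles, model = haplotype_model(),
                            seed, donor_id = "donor1") {
  stopifnot(inherits(family, "gene_family"), inherits(model, "haplotype_model"))
  set.seed(as.integer(seed))
  pair <- model$pair %||%
    sample(names(model$pair_probs), 1L, prob = model$pair_probs)
  n_b <- sum(strsplit(pair, "")[[1L]] == "B")

  genes <- family$genes
  presence <- setNames(rep(TRUE, nrow(genes)), genes$gene_id)
  bgenes <- genes$gene_id[genes$haplotype_assoc == "B_associated"]
  for (g in bgenes) {
    p <- if (length(model$b_presence) > 1L) {
      if (!g %in% names(model$b_presence))
        stopf("b_presence has no probability for %s", g)
      model$b_presence[[g]]
    } else model$b_presence
    presence[[g]] <- n_b > 0L && runif(1L) < (1 - (1 - p)^n_b)
  }

  al <- setNames(vector("list", nrow(genes)), genes$gene_id)
  for (g in genes$gene_id) {
    if (!presence[[g]]) next
    avail <- alleles$allele_name[alleles$gene_id == g]
    if (!length(avail)) stopf("present gene %s has an empty allele list", g)
    al[[g]] <- unique(sample(avail, 2L, replace = TRUE))
  }

  structure(list(donor_id = donor_id, pair = pair,
                 presence = presence, alleles = al),
            class = "donor_genotype")
}

#' Fully-present donor genotype
#'
#' Deterministic genotype carrying every gene of the family with its
#' reference allele — the preset "donor 1" whose repertoire exercises all
#' misassignment routes at once.
#'
#' @inheritParams sample_genotype
#' @return A `donor_genotype`.
#' @export
all_present_genotype <- function(family, alleles, donor_id = "donor1") {
  stopifnot(inherits(family, "gene_family"))
  genes <- family$genes$gene_id
  al <- lapply(genes, function(g) {
    avail <- alleles$allele_name[alleles$gene_id == g]
    if (!length(avail)) stopf("gene %s has an empty allele list", g)
    avail[1L]
  })
  structure(list(donor_id = donor_id, pair = "BB",
                 presence = setNames(rep(TRUE, length(genes)), genes),
                 alleles = setNames(al, genes)),
            class = "donor_genotype")
}

#' @export
print.donor_genotype <- function(x, ...) {
  cat("donor_genotype", x$donor_id, "(haplotypes ", x$pair, "): ",
      sum(x$presence), "/", length(x$presence), " genes present\n", sep = "")
  invisible(x)
}
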