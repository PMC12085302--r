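#' UMI counting from an assignment table
#'
#' Only `unique`-status reads are counted; duplicates are collapsed by
#' exact (barcode, UMI, gene) triple (no UMI error correction — the
#' simulator emits error-free barcodes and UMIs). When a post-filter
#' reference (or explicit gene vector) is supplied, counting is limited
#' to its surviving genes — the mechanism by which an annotation filter
#' silences a gene whose sequence is still in the assembly.
#'
#' @param assignments an `assignment_table` from [align_all()]; read ids
#'   must follow the `r<n>:<barcode>:<umi>` naming convention.
#' @param countable a `reference_set` (post [filter_annotation()]) or
#'   character vector of countable genes; default: every assigned gene.
#' @param cells optional barcode vector fixing matrix rows.
#' @return Object of class `umi_counts`: sparse cells x genes integer
#'   matrix in `$matrix`, plus `$reference` (name) and `$countable`.
#' @export
count_umis <- function(assignments, countable = NULL, cells = NULL) {
  parts <- strsplit(assignments$read_id, ":", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stopf("read name not in r<n>:<barcode>:<umi> form: %s",
          assignments$read_id[bad[1L]])
  genes <- if (inherits(countable, "reference_set"))
    reference_genes(countable)
  else countable %||% sort(unique(assignments$gene_id[
    assignments$status == "unique"]))

  u <- assignments[assignments$status == "unique" &
                     assignments$gene_id %in% genes, , drop = FALSE]
  bc <- vapply(parts, `[[`, character(1), 2L)
  umi <- vapply(parts, `[[`, character(1), 3L)
  ubc <- bc[assignments$status == "unique" & assignments$gene_id %in% genes]
  uumi <- umi[assignments$status == "unique" & assignments$gene_id %in% genes]

  trip <- unique(data.frame(barcode = ubc, umi = uumi, gene = u$gene_id,
                            stringsAsFactors = FALSE))
  cells <- cells %||% sort(unique(bc))
  m <- Matrix::sparseMatrix(
    i = match(trip$barcode, cells),
    j = match(trip$gene, genes),
    x = 1,
    dims = c(length(cells), length(genes)),
    dimnames = list(cells, genes))
  m <- as(m, "CsparseMatrix")
  structure(list(matrix = m,
                 reference = attr(assignments, "reference") %||% "reference",
                 countable = genes),
            class = "umi_counts")
}

#' Write a UMI count matrix as Matrix Market + TSVs
#'
#' Standard cell-by-gene trio: `matrix.mtx` (genes x cells, the
#' single-cell convention), `barcodes.tsv`, `features.tsv`.
#'
#' @param counts a `umi_counts`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_counts_mtx <- function(counts, dir) {
  stopifnot(inherits(counts, "umi_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(counts$matrix), file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts$matrix), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(counts$matrix), file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Reassignment flow between two references
#'
#' Cross-tabulates every read's label (assigned gene, `multimapped` or
#' `unmapped`) under reference A against its label under reference B.
#' Each read occupies exactly one cell, so both marginals sum to the
#' total read count. Computed on reads (not UMIs) by default — the
#' "proportion of reads mapping to each locus" view; `umi = TRUE`
#' collapses to distinct (barcode, UMI, label) first.
#'
#' Also reports the signed assigned-count change
#' `(unique_B - unique_A) / unique_A`: the analog of the reduction in
#' family-specific counts upon realignment to a fuller reference, driven
#' by newly introduced homologs turning unique hits into discarded
#' multi-mapping ties.
#'
#' @param assignments_a,assignments_b `assignment_table`s over the same
#'   read ids.
#' @param umi collapse to UMI level first (default FALSE).
#' @return Object of class `reassignment_flow`: `$matrix` (labels_A x
#'   labels_B read counts), `$signed_change`, `$n_reads`.
#' @export
compare_references <- function(assignments_a, assignments_b, umi = FALSE) {
  a <- assignments_a; b <- assignments_b
  if (nrow(a) != nrow(b) || !setequal(a$read_id, b$read_id))
    stopf("assignment tables cover different read ids")
  b <- b[match(a$read_id, b$read_id), ]
  lab <- function(x) ifelse(x$status == "unique", x$gene_id, x$status)
  la <- lab(a); lb <- lab(b)
  if (umi) {
    key <- sub("^[^:]+:", "", a$read_id)   # barcode:umi
    keep <- !duplicated(paste(key, la, lb))
    la <- la[keep]; lb <- lb[keep]
  }
  levs <- sort(unique(c(la, lb, "multimapped", "unmapped")))
  m <- table(factor(la, levs), factor(lb, levs))
  ua <- sum(a$status == "unique"); ub <- sum(b$status == "unique")
  structure(list(matrix = unclass(m),
                 signed_change = if (ua > 0) (ub - ua) / ua else NA_real_,
                 n_reads = nrow(a),
                 reference_a = attr(a, "reference") %||% "A",
                 reference_b = attr(b, "reference") %||% "B"),
            class = "reassignment_flow")
}

#' @export
print.reassignment_flow <- function(x, ...) {
  cat("reassignment_flow:", x$n_reads, "reads,",
      x$reference_a, "->", x$reference_b,
      sprintf("(signed unique-count change %+.1f%%)\n",
              100 * x$signed_change))
  print(x$matrix)
  invisible(x)
}

#' Misassignment report against simulation truth
#'
#' Joins assignments to the truth table and reports, per true gene, the
#' distribution of assigned labels (each row sums to 1), the overall
#' misassigned fraction (reads uniquely assigned to a gene other than
#' their true gene), and — when receptor classes are supplied — the
#' inhibitory overcount: unique assignments landing on inhibitory-class
#' genes minus truth reads originating from those genes, the
#' activating-to-inhibitory inflation the restricted reference produces.
#'
#' @param assignments an `assignment_table`.
#' @param truth a `sim_reads` data.frame (or truth TSV data.frame).
#' @param classes optional named vector `gene_id -> receptor_class`.
#' @return Object of class `misassignment_report`: `$by_true_gene`
#'   (fraction matrix), `$misassigned_fraction`,
#'   `$inhibitory_overcount` (NA without classes), `$n_reads`.
#' @export
misassignment_report <- function(assignments, truth, classes = NULL) {
  if (!nrow(assignments)) {
    return(structure(list(by_true_gene = matrix(numeric(0), 0, 0),
                          misassigned_fraction = NA_real_,
                          inhibitory_overcount = NA_real_, n_reads = 0L),
                     class = "misassignment_report"))
  }
  i <- match(assignments$read_id, truth$read_id)
  if (any(is.na(i))) stopf("truth table does not cover all reads")
  tg <- truth$true_gene[i]
  lab <- ifelse(assignments$status == "unique", assignments$gene_id,
                assignments$status)
  levs <- sort(unique(c(tg, lab)))
  tab <- table(factor(tg, levs), factor(lab, levs))
  by_true <- prop.table(tab[rowSums(tab) > 0, , drop = FALSE], margin = 1)

  mis <- assignments$status == "unique" & assignments$gene_id != tg
  over <- NA_real_
  if (!is.null(classes)) {
    inh <- names(classes)[classes == "inhibitory"]
    over <- sum(assignments$status == "unique" &
                  assignments$gene_id %in% inh) - sum(tg %in% inh)
  }
  structure(list(by_true_gene = unclass(by_true),
                 misassigned_fraction = mean(mis),
                 inhibitory_overcount = over,
                 n_reads = nrow(assignments)),
            class = "misassignment_report")
}

#' Co-expression patterns
#'
#' Per cell, the expressed set is the genes with UMI count
#' `>= min_count`; patterns are ranked by the number of cells showing
#' exactly that set, ties broken by lexicographic gene-set order. Cells
#' with no expressed gene are excluded, so pattern cell counts sum to
#' the number of cells expressing at least one gene.
#'
#' @param counts a `umi_counts`.
#' @param min_count expression threshold (>= 1, default 1).
#' @return data.frame: `pattern` (gene ids joined by `"+"`), `n_genes`,
#'   `n_cells`, `rank`.
#' @export
coexpression_patterns <- function(counts, min_count = 1L) {
  stopifnot(inherits(counts, "umi_counts"))
  if (min_count < 1L) stopf("min_count must be >= 1")
  m <- counts$matrix >= min_count
  sets <- apply(m, 1L, function(row) paste(colnames(m)[row], collapse = "+"))
  sets <- sets[nzchar(sets)]
  if (!length(sets))
    return(data.frame(pattern = character(0), n_genes = integer(0),
                      n_cells = integer(0), rank = integer(0)))
  tab <- table(sets)
  out <- data.frame(pattern = names(tab), n_cells = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$n_genes <- lengths(strsplit(out$pattern, "+", fixed = TRUE))
  out <- out[order(-out$n_cells, out$pattern), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("pattern", "n_genes", "n_cells", "rank")]
}

#' Infer gene presence from a count matrix
#'
#' A gene is called present iff at least `min_cells` cells carry at
#' least `min_umis` of its UMIs — the presence/absence readout compared
#' against the simulated donor genotype in recovery experiments.
#'
#' @param counts a `umi_counts`.
#' @param min_umis,min_cells thresholds (>= 1).
#' @return named logical vector over the matrix's genes.
#' @export
infer_genotype <- function(counts, min_umis = 1L, min_cells = 2L) {
  stopifnot(inherits(counts, "umi_counts"))
  if (min_umis < 1L || min_cells < 1L) stopf("thresholds must be >= 1")
  pos_cells <- Matrix::colSums(counts$matrix >= min_umis)
  setNames(pos_cells >= min_cells, colnames(counts$matrix))
}
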