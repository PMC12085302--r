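#' Per-exon pairwise identity matrices
#'
#' Position-wise identity (matching positions / exon length) between
#' every pair of coordinate-aligned sequences, per exon. This is the
#' homology landscape that predicts where misassignment and
#' multi-mapping occur: exon blocks of near-1 identity between two genes
#' are regions whose reads cannot tell them apart.
#'
#' @param x a `gene_family`, or a named character vector of equal-length
#'   sequences.
#' @param plan an `exon_plan` (taken from the family when `x` is one).
#' @return Named list (one symmetric genes x genes matrix per exon
#'   label, unit diagonal), class `exon_identity`.
#' @export
exon_identity <- function(x, plan = NULL) {
  if (inherits(x, "gene_family")) {
    plan <- x$exon_plan
    seqs <- x$sequences
  } else {
    seqs <- x
    if (is.null(plan)) stopf("an exon_plan is required for raw sequences")
  }
  if (length(unique(nchar(seqs))) != 1L)
    stopf("sequences must be equal-length (coordinate-aligned)")
  if (nchar(seqs[[1L]]) != plan_length(plan))
    stopf("sequence length does not match the exon plan")
  ids <- names(seqs)
  mats <- lapply(exon_ranges(plan)$exon, function(e) {
    m <- diag(1, length(ids))
    dimnames(m) <- list(ids, ids)
    m
  })
  names(mats) <- exon_ranges(plan)$exon
  rng <- exon_ranges(plan)
  ivec <- lapply(seqs, utf8ToInt)
  for (a in seq_along(ids)) for (b in seq_len(a - 1L)) {
    eq <- ivec[[a]] == ivec[[b]]
    for (i in seq_len(nrow(rng))) {
      span <- (rng$start[i] + 1L):rng$end[i]
      v <- mean(eq[span])
      mats[[i]][a, b] <- v
      mats[[i]][b, a] <- v
    }
  }
  structure(mats, class = "exon_identity")
}

#' Tidy an exon-identity object
#' @param idm an `exon_identity`.
#' @return data.frame `gene_a`, `gene_b`, `exon`, `identity` (unordered
#'   pairs, a < b).
#' @export
exon_identity_table <- function(idm) {
  stopifnot(inherits(idm, "exon_identity"))
  do.call(rbind, lapply(names(idm), function(e) {
    m <- idm[[e]]
    ut <- which(upper.tri(m), arr.ind = TRUE)
    data.frame(gene_a = rownames(m)[ut[, 1L]],
               gene_b = colnames(m)[ut[, 2L]],
               exon = e, identity = m[ut], stringsAsFactors = FALSE)
  }))
}

#' Diagnostic positions of a locus group
#'
#' For a group of coordinate-aligned sequences (the genes/alleles that
#' can be confused at one locus), finds exactly the positions where at
#' least two distinct bases occur, together with the base-to-member
#' support map. A position is gene-diagnostic for member `g` when one of
#' its bases is carried only by `g` — observing that base in a read
#' attributes the read to `g`.
#'
#' @param seqs named character vector (>= 2 equal-length sequences; a
#'   single-sequence group yields an empty set with a warning).
#' @return Object of class `diagnostic_positions`: data.frame `pos`
#'   (0-based), `base`, `members` (comma-joined), `diagnostic_for`
#'   (member name when the base is private, else NA). The full
#'   position x member base matrix is in the `base_matrix` attribute.
#' @export
find_diagnostic_positions <- function(seqs) {
  if (length(seqs) < 2L) {
    warnf("single-sequence group: no diagnostic positions")
    out <- data.frame(pos = integer(0), base = character(0),
                      members = character(0),
                      diagnostic_for = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "base_matrix") <- matrix(character(0), 0, length(seqs),
                                       dimnames = list(NULL, names(seqs)))
    class(out) <- c("diagnostic_positions", "data.frame")
    return(out)
  }
  if (length(unique(nchar(seqs))) != 1L)
    stopf("group sequences must be equal-length")
  mat <- do.call(cbind, strsplit(seqs, "", fixed = TRUE))  # pos x member
  colnames(mat) <- names(seqs)
  varying <- which(apply(mat, 1L, function(r) length(unique(r)) > 1L))
  rows <- list()
  for (p in varying) {
    for (b in unique(mat[p, ])) {
      carriers <- colnames(mat)[mat[p, ] == b]
      rows[[length(rows) + 1L]] <- data.frame(
        pos = p - 1L, base = b,
        members = paste(carriers, collapse = ","),
        diagnostic_for = if (length(carriers) == 1L) carriers
                         else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pos = integer(0), base = character(0),
               members = character(0), diagnostic_for = character(0),
               stringsAsFactors = FALSE)
  attr(out, "base_matrix") <- mat[varying, , drop = FALSE]
  attr(out, "varying_pos") <- varying - 1L
  class(out) <- c("diagnostic_positions", "data.frame")
  out
}

#' Classify locus-assigned reads by their diagnostic bases
#'
#' The polymorphism inspection applied to reads mapped to one locus:
#' each read's observed bases at the diagnostic positions it covers are
#' compared with every candidate source. A source supports the read if
#' it agrees at every covered diagnostic position (and at least
#' `min_informative` of them); a read with a single supporting source is
#' classified to it, a read covering no diagnostic position is
#' uninformative (as is one whose support is ambiguous between >= 2
#' sources), and a read contradicting every source is conflicting —
#' with error-free reads conflicts cannot occur.
#'
#' @param reads data.frame with `read_id`, `start` (0-based offset of
#'   the read on the locus coordinate system) and `sequence`; reads with
#'   missing `start` raise an error.
#' @param diagnostics a `diagnostic_positions` for the locus group.
#' @param min_informative minimum covered diagnostic positions for a
#'   classification (default 1: a single covered diagnostic base
#'   classifies).
#' @return Object of class `locus_composition`: `$fractions` (named,
#'   sources then `uninformative` and `conflicting`; sums to 1),
#'   `$per_read` (`read_id`, `call`), `$n_reads`.
#' @export
classify_locus_reads <- function(reads, diagnostics, min_informative = 1L) {
  stopifnot(inherits(diagnostics, "diagnostic_positions"))
  if (any(is.na(reads$start)))
    stopf("read without an alignment offset: %s",
          reads$read_id[which(is.na(reads$start))[1L]])
  bm <- attr(diagnostics, "base_matrix")
  pos <- attr(diagnostics, "varying_pos") %||% integer(0)
  members <- colnames(bm)
  call <- character(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    st <- reads$start[i]
    len <- nchar(reads$sequence[i])
    cov <- which(pos >= st & pos < st + len)
    if (!length(cov) || length(cov) < min_informative) {
      call[i] <- "uninformative"; next
    }
    obs <- substring(reads$sequence[i], pos[cov] - st + 1L,
                     pos[cov] - st + 1L)
    agree <- vapply(members, function(m)
      all(bm[cov, m] == obs), logical(1L))
    support <- members[agree]
    call[i] <- if (length(support) == 1L) support
               else if (length(support) == 0L) "conflicting"
               else "uninformative"
  }
  levs <- c(members, "uninformative", "conflicting")
  frac <- table(factor(call, levels = levs)) / max(1L, nrow(reads))
  structure(list(fractions = c(unclass(frac)),
                 per_read = data.frame(read_id = reads$read_id,
                                       call = call,
                                       stringsAsFactors = FALSE),
                 n_reads = nrow(reads)),
            class = "locus_composition")
}

#' Predict the misassignment sink of an absent gene
#'
#' Slides a read-length window along the coordinate-aligned sequences
#' and computes the maximum windowed identity between the absent gene
#' and every reference gene. If the best reference gene reaches the
#' identity threshold (the mapper's acceptance floor translated to
#' identity), it is the predicted sink — the locus that will capture the
#' absent gene's reads; otherwise the prediction is `UNMAPPED` (the
#' reads are lost rather than misassigned).
#'
#' @param absent_gene gene id absent from the reference.
#' @param family the `gene_family` providing its sequence.
#' @param reference a `reference_set` not containing `absent_gene`.
#' @param identity_window window length (defaults to the read length of
#'   the preset, 90 nt).
#' @param threshold windowed-identity floor; the default 0.9 corresponds
#'   to `min_score_fraction = 0.8` under +1/-1 scoring
#'   (`1 - 2 * mismatch_rate >= 0.8`).
#' @return Object of class `sink_prediction`: `$absent_gene`, `$sink`
#'   (gene id or `"UNMAPPED"`), `$max_identity`, `$per_gene` (named max
#'   windowed identities), `$mean_identity` (whole-transcript
#'   identities, used to break windowed ties), `$decisive` (TRUE when
#'   one reference gene is clearly nearest, or none passes the
#'   threshold; an indecisive prediction signals that the absent gene's
#'   reads will mostly be discarded as multi-mapped rather than sunk
#'   into a single locus), `$threshold`, `$window`.
#' @export
predict_sink <- function(absent_gene, family, reference,
                         identity_window = 90L, threshold = 0.9) {
  stopifnot(inherits(family, "gene_family"),
            inherits(reference, "reference_set"))
  if (absent_gene %in% reference_genes(reference))
    stopf("%s is present in the reference; sink prediction applies to absent genes",
          absent_gene)
  if (!absent_gene %in% names(family$sequences))
    stopf("gene %s not in family", absent_gene)
  av <- utf8ToInt(family$sequences[[absent_gene]])
  w <- as.integer(identity_window)
  if (w > length(av)) stopf("identity_window exceeds transcript length")

  tx <- reference$transcripts
  stats_tx <- vapply(tx$sequence, function(s) {
    bv <- utf8ToInt(s)
    eq <- as.integer(av == bv)
    cs <- cumsum(eq)
    wins <- cs[w:length(eq)] - c(0L, cs)[seq_len(length(eq) - w + 1L)]
    c(max(wins) / w, mean(eq))
  }, numeric(2L), USE.NAMES = FALSE)
  per_gene <- tapply(stats_tx[1L, ], tx$gene_id, max)
  mean_gene <- tapply(stats_tx[2L, ], tx$gene_id, max)
  ## windowed identity ranks candidates; whole-transcript mean identity
  ## breaks windowed ties (several genes can share a perfect conserved
  ## window while only one is the genuine nearest homolog)
  ord <- order(-per_gene, -mean_gene)
  best <- ord[1L]
  sink <- if (per_gene[[best]] >= threshold) names(per_gene)[best] else "UNMAPPED"
  ## a prediction is decisive when the reads have one clearly nearest
  ## gene (or none at all); for a gene near-equidistant from several
  ## references the simulated majority fate is multi-mapping instead
  margin <- if (length(ord) > 1L)
    mean_gene[[best]] - max(mean_gene[ord[-1L]]) else Inf
  structure(list(absent_gene = absent_gene, sink = sink,
                 max_identity = unname(per_gene[[best]]),
                 per_gene = setNames(as.numeric(per_gene), names(per_gene)),
                 mean_identity = setNames(as.numeric(mean_gene),
                                          names(mean_gene)),
                 decisive = sink == "UNMAPPED" || margin >= 0.01,
                 threshold = threshold, window = w),
            class = "sink_prediction")
}

#' @export
print.sink_prediction <- function(x, ...) {
  cat(sprintf("sink_prediction: %s -> %s (max windowed identity %.3f, threshold %.2f, window %d)\n",
              x$absent_gene, x$sink, x$max_identity, x$threshold, x$window))
  invisible(x)
}
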