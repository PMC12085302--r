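#' Brute-force alignment oracle
#'
#' Independent of the seed-and-extend path: for every read and
#' transcript it scans *all* diagonals on which the full read fits and
#' scores each one exhaustively, returning the optimal ungapped score
#' per transcript. Used to validate the mapper (the mapper can only miss
#' a diagonal that carries no exact k-mer seed; wherever a seed exists
#' the two must agree).
#'
#' @param read_seqs character vector of read sequences.
#' @param reference a `reference_set`.
#' @param scoring a [scoring_scheme()].
#' @return data.frame: `read` (index), `transcript_id`, `gene_id`,
#'   `start` (0-based optimal diagonal, smallest on ties), `score`,
#'   `n_mismatches`, thresholded exactly like the mapper.
#' @export
oracle_align <- function(read_seqs, reference, scoring = scoring_scheme()) {
  stopifnot(inherits(reference, "reference_set"))
  tx <- reference$transcripts
  tx_int <- lapply(tx$sequence, utf8ToInt)
  rows <- vector("list", length(read_seqs) * nrow(tx))
  n_out <- 0L
  for (r in seq_along(read_seqs)) {
    rv <- utf8ToInt(read_seqs[r])
    L <- length(rv)
    min_score <- ceiling(scoring$min_score_fraction * scoring$match * L)
    for (t in seq_len(nrow(tx))) {
      tv <- tx_int[[t]]
      D <- length(tv) - L + 1L
      if (D < 1L) next
      mm <- mismatches_all_diagonals(rv, tv)
      sc <- scoring$match * (L - mm) + scoring$mismatch * mm
      best <- max(sc)
      if (best < min_score) next
      d0 <- which(sc == best)[1L]  # smallest diagonal on ties
      n_out <- n_out + 1L
      rows[[n_out]] <- data.frame(
        read = r, transcript_id = tx$transcript_id[t],
        gene_id = tx$gene_id[t], start = d0 - 1L, score = best,
        n_mismatches = mm[d0], stringsAsFactors = FALSE)
    }
  }
  if (!n_out)
    return(data.frame(read = integer(0), transcript_id = character(0),
                      gene_id = character(0), start = integer(0),
                      score = integer(0), n_mismatches = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows[seq_len(n_out)])
}

## mismatch count of the full read at every valid diagonal
## (vectorized sliding comparison; integer-coded sequences)
mismatches_all_diagonals <- function(rv, tv) {
  L <- length(rv); D <- length(tv) - L + 1L
  idx <- outer(seq_len(D) - 1L, seq_len(L), `+`)   # D x L transcript positions
  matrix_tx <- matrix(tv[idx], nrow = D)
  as.integer(rowSums(matrix_tx != matrix(rv, nrow = D, ncol = L, byrow = TRUE)))
}

#' Oracle assignments for a read set
#'
#' Applies the identical tie rule ([assign_read()] semantics) to the
#' oracle's per-transcript optimal scores.
#'
#' @inheritParams oracle_align
#' @param read_ids optional read names.
#' @param tie_margin see [assign_read()].
#' @return `assignment_table`-shaped data.frame.
#' @export
oracle_assign <- function(read_seqs, reference, scoring = scoring_scheme(),
                          tie_margin = 0, read_ids = NULL) {
  ids <- read_ids %||% sprintf("r%07d", seq_along(read_seqs))
  hits <- oracle_align(read_seqs, reference, scoring)
  out <- assign_hits_table(hits, ids, tie_margin)
  class(out) <- c("assignment_table", "data.frame")
  out
}

#' Does a diagonal carry an exact k-mer seed?
#'
#' Brute-force check (independent of the index): TRUE iff read and
#' transcript share an exact k-length run on diagonal `start`.
#'
#' @param read_seq read sequence.
#' @param tx_seq transcript sequence.
#' @param start 0-based diagonal offset.
#' @param k k-mer length.
#' @return logical.
#' @export
has_seed_on_diagonal <- function(read_seq, tx_seq, start, k) {
  rv <- utf8ToInt(read_seq)
  tv <- utf8ToInt(tx_seq)
  L <- length(rv)
  if (start < 0L || start + L > length(tv)) return(FALSE)
  eq <- rv == tv[(start + 1L):(start + L)]
  r <- rle(eq)
  any(r$values & r$lengths >= k)
}
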