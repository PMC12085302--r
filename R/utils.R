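## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

DNA_BASES <- c("A", "C", "G", "T")

#' Derive a stage seed from a master seed
#'
#' Per-stage seeds are a deterministic function of the master seed and a
#' stage name, so any stage of a pipeline run can be reproduced in
#' isolation. Result always fits in a 32-bit signed integer.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000000007
  as.integer(((abs(master) %% 1000003) * 1009 + h %% 1000003) %% 2147483647)
}

## random DNA string of length n
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## encode non-negative integers as fixed-width DNA (base-4 digits -> ACGT);
## distinct integers give distinct sequences, used for collision-free
## barcodes/UMIs
int_to_dna <- function(x, width) {
  m <- matrix("A", nrow = length(x), ncol = width)
  v <- x
  for (j in seq(width, 1L)) {
    m[, j] <- DNA_BASES[(v %% 4) + 1L]
    v <- v %/% 4
  }
  apply(m, 1L, paste, collapse = "")
}

## substitute: each position gets a base drawn uniformly from the 3 others
mutate_positions <- function(chars, pos) {
  if (length(pos) == 0L) return(chars)
  old <- chars[pos]
  pick <- function(b) sample(setdiff(DNA_BASES, b), 1L)
  chars[pos] <- vapply(old, pick, character(1L), USE.NAMES = FALSE)
  chars
}

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]
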