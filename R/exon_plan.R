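#' Exon plan for a coordinate-aligned gene family
#'
#' An exon plan fixes the shared exon structure of every gene in a family:
#' ordered exon labels and positive exon lengths (nt). All sequences built
#' on a plan have length `sum(lengths)` and share coordinates, so
#' position-wise identity and diagnostic-position extraction are exact.
#' Coordinates are 0-based, half-open throughout the package.
#'
#' @param lengths positive integer vector of exon lengths (nt).
#' @param labels unique character labels, one per exon; defaults to
#'   `"1"`, `"2"`, ...
#' @return An object of class `exon_plan`.
#' @examples
#' plan <- exon_plan(c(50, 100, 75))
#' plan_length(plan)
#' @export
exon_plan <- function(lengths, labels = as.character(seq_along(lengths))) {
  lengths <- as.integer(lengths)
  if (length(lengths) == 0L) stopf("exon plan needs at least one exon")
  if (any(is.na(lengths)) || any(lengths <= 0L))
    stopf("all exon lengths must be positive integers")
  labels <- as.character(labels)
  if (length(labels) != length(lengths) || anyDuplicated(labels))
    stopf("exon labels must be unique and match the number of lengths")
  structure(list(labels = labels, lengths = setNames(lengths, labels)),
            class = "exon_plan")
}

#' @rdname exon_plan
#' @param plan an `exon_plan`.
#' @export
plan_length <- function(plan) {
  stopifnot(inherits(plan, "exon_plan"))
  sum(plan$lengths)
}

#' Exon coordinate table
#'
#' @param plan an `exon_plan`.
#' @return data.frame with `exon`, `start` and `end` (0-based, half-open
#'   transcript offsets).
#' @export
exon_ranges <- function(plan) {
  stopifnot(inherits(plan, "exon_plan"))
  ends <- cumsum(plan$lengths)
  data.frame(exon = plan$labels,
             start = c(0L, head(ends, -1L)),
             end = as.integer(ends),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.exon_plan <- function(x, ...) {
  cat("exon plan:", length(x$labels), "exons,", plan_length(x), "nt\n")
  print(x$lengths)
  invisible(x)
}

#' KIR-like 9-exon plan
#'
#' Exon lengths approximating a three-domain KIR cDNA (~1.3 kb): short
#' leader exons 1/2, the three Ig-domain exons 3/4/5, short stem/
#' transmembrane exons 6/7/8 and a cytoplasmic-tail/3' exon 9.
#'
#' @return An `exon_plan` with exons labelled `"1"`..`"9"`.
#' @export
kir_exon_plan <- function() {
  exon_plan(c(34L, 36L, 285L, 300L, 294L, 51L, 102L, 53L, 126L),
            labels = as.character(1:9))
}

#' Default per-exon inter-gene identity profile
#'
#' High identity (0.97) at the short conserved exons 1/2/6/7/8 and lower
#' identity (0.90) at the Ig-domain exons 3/4/5 and the 3' exon 9,
#' reproducing the conserved/variable exon contrast of the KIR family.
#'
#' @param plan an `exon_plan` (defaults to [kir_exon_plan()]).
#' @return Named numeric vector of target pairwise identities in `[0, 1]`.
#' @export
kir_identity_profile <- function(plan = kir_exon_plan()) {
  prof <- setNames(rep(0.90, length(plan$labels)), plan$labels)
  conserved <- intersect(c("1", "2", "6", "7", "8"), plan$labels)
  prof[conserved] <- 0.97
  prof
}

## validate a profile against a plan
check_identity_profile <- function(profile, plan) {
  if (!all(plan$labels %in% names(profile)))
    stopf("identity profile missing exons: %s",
          paste(setdiff(plan$labels, names(profile)), collapse = ", "))
  vals <- profile[plan$labels]
  if (any(is.na(vals)) || any(vals < 0) || any(vals > 1))
    stopf("identity profile values must lie in [0, 1]")
  vals
}
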