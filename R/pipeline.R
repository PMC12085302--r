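#' Preset experiment configuration
#'
#' The study conditions: the 16-gene KIR-like preset family, a donor
#' carrying every gene with its reference allele, 800 cells at 25%
#' positive-cell frequency and 3 mean molecules per positive gene, two
#' 90-nt 5'-tag reads per molecule (~1.9e4 reads), 0.5% per-base
#' substitution error, and the default mapper (k = 21, +1/-1 scoring,
#' 0.8 acceptance floor, exact ties discarded as multi-mapped).
#'
#' @param seed master seed; all stage seeds derive from it via
#'   [derive_seed()].
#' @param ... overrides for any config field.
#' @return list of class `run_config`.
#' @export
kir_preset_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_cells = 800L, pos_freq = 0.25, gene_mean = 3,
    read_length = 90L, error_rate = 0.005, reads_per_molecule = 2L,
    start_model = list(type = "geometric", p = 0.02),
    n_alleles_per_gene = 1L, allele_divergence = 0.002,
    genotype = "all_present",
    k = 21L, match = 1L, mismatch = -1L, min_score_fraction = 0.8,
    tie_margin = 0,
    allowed_biotypes = "functional",
    min_umis = 1L, min_cells = 2L, min_count = 1L,
    sink_threshold = 0.9)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with any subset of the [kir_preset_config()]
#'   keys; unknown keys raise an error listing them.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(kir_preset_config, y)
}

#' Run the two-arm misassignment experiment
#'
#' The end-to-end workflow: simulate a donor's 5'-tag reads once, align
#' the identical read set to the restricted (GRCh38-like, 7-gene) and
#' full (all-KIR, 16-gene) references, quantify UMIs under each (the
#' restricted arm counts only the biotype-filtered 6-gene annotation,
#' while alignment still sees all 7 transcripts — the assembly-versus-
#' annotation distinction), and derive the comparison artifacts:
#' reassignment flow, misassignment reports, co-expression patterns,
#' genotype recovery and sink predictions. Conservation invariants
#' (status counts and flow marginals equal the read total) are asserted
#' on every run.
#'
#' @param config a `run_config` (from [kir_preset_config()]) or the path
#'   to a YAML config.
#' @param out_dir optional output directory; when given, FASTQ, truth
#'   table, references (FASTA + GTF), count matrices (Matrix Market),
#'   flow/report/identity TSVs, the echoed config and a run log are
#'   written there.
#' @return list of class `experiment_result` with the in-memory objects
#'   (`family`, `alleles`, `genotype`, `truth`, `reads`, `ref_restricted`,
#'   `ref_restricted_filtered`, `ref_full`, `assign_restricted`,
#'   `assign_full`, `counts_restricted`, `counts_full`, `flow`,
#'   `report_restricted`, `report_full`, `coexpression`,
#'   `genotype_calls`, `sink_predictions`, `config`) and, when `out_dir`
#'   is given, `paths`.
#' @export
run_experiment <- function(config = kir_preset_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, paste0(format(Sys.time(), "%H:%M:%S "), msg))
    invisible(msg)
  }

  say("master seed %d", cfg$seed)
  family <- kir_preset_family(derive_seed(cfg$seed, "family"))
  alleles <- generate_alleles(family, cfg$n_alleles_per_gene,
                              cfg$allele_divergence,
                              seed = derive_seed(cfg$seed, "alleles"))
  genotype <- if (identical(cfg$genotype, "all_present"))
    all_present_genotype(family, alleles)
  else sample_genotype(family, alleles, haplotype_model(),
                       seed = derive_seed(cfg$seed, "genotype"))
  say("genotype %s: %d/%d genes present", genotype$donor_id,
      sum(genotype$presence), length(genotype$presence))

  truth <- simulate_expression(genotype, cfg$n_cells, cfg$pos_freq,
                               cfg$gene_mean,
                               seed = derive_seed(cfg$seed, "expression"))
  reads <- simulate_reads(truth, genotype, alleles,
                          read_length = cfg$read_length,
                          error_rate = cfg$error_rate,
                          reads_per_molecule = cfg$reads_per_molecule,
                          start_model = cfg$start_model,
                          seed = derive_seed(cfg$seed, "reads"))
  say("simulated %d reads from %d molecules",
      nrow(reads), nrow(reads) / max(1L, cfg$reads_per_molecule))

  ref_r <- restricted_reference(family)
  ref_rf <- filter_annotation(ref_r, cfg$allowed_biotypes)
  ref_f <- full_reference(family)
  say("references: restricted %d genes (%d countable after filter), full %d genes",
      length(reference_genes(ref_r)), length(reference_genes(ref_rf)),
      length(reference_genes(ref_f)))

  scor <- scoring_scheme(cfg$match, cfg$mismatch, cfg$min_score_fraction)
  asg_r <- align_all(reads, ref_r, scor, k = cfg$k, tie_margin = cfg$tie_margin)
  asg_f <- align_all(reads, ref_f, scor, k = cfg$k, tie_margin = cfg$tie_margin)
  for (asg in list(asg_r, asg_f)) {
    stopifnot(sum(attr(asg, "status_counts")) == nrow(reads))
  }
  say("restricted arm: %s", paste(names(attr(asg_r, "status_counts")),
                                  attr(asg_r, "status_counts"),
                                  collapse = ", "))
  say("full arm: %s", paste(names(attr(asg_f, "status_counts")),
                            attr(asg_f, "status_counts"), collapse = ", "))

  cells <- truth$cells
  counts_r <- count_umis(asg_r, countable = ref_rf, cells = cells)
  counts_f <- count_umis(asg_f, countable = ref_f, cells = cells)

  flow <- compare_references(asg_r, asg_f)
  stopifnot(sum(rowSums(flow$matrix)) == nrow(reads),
            sum(colSums(flow$matrix)) == nrow(reads))
  say("signed unique-count change full vs restricted: %+.2f%%",
      100 * flow$signed_change)

  classes <- setNames(family$genes$receptor_class, family$genes$gene_id)
  rep_r <- misassignment_report(asg_r, reads, classes)
  rep_f <- misassignment_report(asg_f, reads, classes)
  coex <- coexpression_patterns(counts_f, cfg$min_count)
  calls <- infer_genotype(counts_f, cfg$min_umis, cfg$min_cells)

  absent <- setdiff(family$genes$gene_id, reference_genes(ref_r))
  sinks <- lapply(absent, predict_sink, family = family, reference = ref_r,
                  identity_window = cfg$read_length,
                  threshold = cfg$sink_threshold)
  names(sinks) <- absent

  res <- list(family = family, alleles = alleles, genotype = genotype,
              truth = truth, reads = reads,
              ref_restricted = ref_r, ref_restricted_filtered = ref_rf,
              ref_full = ref_f,
              assign_restricted = asg_r, assign_full = asg_f,
              counts_restricted = counts_r, counts_full = counts_f,
              flow = flow, report_restricted = rep_r, report_full = rep_f,
              coexpression = coex, genotype_calls = calls,
              sink_predictions = sinks, config = cfg, log = log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(...) file.path(out_dir, ...)
    write_reads_fastq(reads, p("reads.fastq"))
    write_truth_table(reads, p("truth.tsv"))
    write_reference(ref_r, p("restricted.fa"), p("restricted.gtf"))
    write_reference(ref_f, p("full.fa"), p("full.gtf"))
    write.table(asg_r, p("assignments_restricted.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(asg_f, p("assignments_full.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_counts_mtx(counts_r, p("counts_restricted"))
    write_counts_mtx(counts_f, p("counts_full"))
    write.table(as.data.frame(flow$matrix), p("flow.tsv"), sep = "\t",
                quote = FALSE)
    write.table(exon_identity_table(exon_identity(family)),
                p("exon_identity.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(coex, p("coexpression.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    sink_df <- data.frame(
      absent_gene = names(sinks),
      sink = vapply(sinks, `[[`, character(1), "sink"),
      max_identity = vapply(sinks, `[[`, numeric(1), "max_identity"))
    write.table(sink_df, p("sink_predictions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    yaml::write_yaml(unclass(cfg), p("config.yaml"))
    writeLines(log, p("run.log"))
    res$paths <- list(
      fastq = p("reads.fastq"), truth = p("truth.tsv"),
      restricted_fasta = p("restricted.fa"), restricted_gtf = p("restricted.gtf"),
      full_fasta = p("full.fa"), full_gtf = p("full.gtf"),
      assignments_restricted = p("assignments_restricted.tsv"),
      assignments_full = p("assignments_full.tsv"),
      counts_restricted = p("counts_restricted"),
      counts_full = p("counts_full"),
      flow = p("flow.tsv"), exon_identity = p("exon_identity.tsv"),
      coexpression = p("coexpression.tsv"),
      sink_predictions = p("sink_predictions.tsv"),
      config = p("config.yaml"), log = p("run.log"))
    missing <- !vapply(res$paths, file.exists, logical(1L))
    if (any(missing))
      stopf("artifact(s) not written: %s",
            paste(names(res$paths)[missing], collapse = ", "))
  }
  class(res) <- "experiment_result"
  res
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("experiment_result: seed", x$config$seed, "\n")
  cat(" reads:", nrow(x$reads), "\n")
  cat(" restricted arm:", paste(names(attr(x$assign_restricted, "status_counts")),
                                attr(x$assign_restricted, "status_counts"),
                                collapse = ", "), "\n")
  cat(" full arm:      ", paste(names(attr(x$assign_full, "status_counts")),
                                attr(x$assign_full, "status_counts"),
                                collapse = ", "), "\n")
  cat(sprintf(" signed unique-count change: %+.2f%%\n",
              100 * x$flow$signed_change))
  invisible(x)
}
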