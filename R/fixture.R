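#' Canonical KIR gene-content table
#'
#' The fixed facts about the human KIR gene complex that the package's
#' reference presets encode: gene names, annotation biotype, receptor
#' class, haplotype association, and whether the gene is present in the
#' GRCh37/38 reference assemblies. Seven KIR genes are in GRCh38
#' (KIR2DL1/L3/L4, KIR2DS4, KIR3DL1/L2/L3); the complete family holds 14
#' functional genes plus the two framework pseudogenes KIR2DP1/KIR3DP1.
#' KIR2DS4 carries the Ensembl biotype "polymorphic pseudogene", which is
#' what removes it from pseudogene-filtered annotations even though it is
#' in the assembly.
#'
#' KIR2DL5A and KIR2DL5B are a single entry under the default `"merged"`
#' convention (used for the 14 + 2 gene counts) and two entries under
#' `"split"` (the genotyping-panel display convention). Both conventions
#' are carried because gene-content counts in the field use either.
#'
#' @param convention `"merged"` (default) or `"split"` handling of
#'   KIR2DL5A/B.
#' @return data.frame with columns `gene_id`, `biotype`
#'   (`functional` / `polymorphic_pseudogene` / `pseudogene`),
#'   `receptor_class` (`inhibitory` / `activating` / `framework_pseudogene`),
#'   `haplotype_assoc` (`A_fixed` / `B_associated` / `framework`) and
#'   `in_grch38` (logical).
#' @examples
#' fx <- kir_fixture()
#' sum(fx$in_grch38)                      # 7 genes in GRCh38
#' sum(fx$biotype != "pseudogene")        # 14 functional genes
#' @export
kir_fixture <- function(convention = c("merged", "split")) {
  convention <- match.arg(convention)
  g <- function(id, bio, cls, hap, g38)
    data.frame(gene_id = id, biotype = bio, receptor_class = cls,
               haplotype_assoc = hap, in_grch38 = g38,
               stringsAsFactors = FALSE)
  fx <- rbind(
    g("KIR2DL1", "functional",             "inhibitory",           "A_fixed",      TRUE),
    g("KIR2DL2", "functional",             "inhibitory",           "B_associated", FALSE),
    g("KIR2DL3", "functional",             "inhibitory",           "A_fixed",      TRUE),
    g("KIR2DL4", "functional",             "inhibitory",           "framework",    TRUE),
    g("KIR2DL5", "functional",             "inhibitory",           "B_associated", FALSE),
    g("KIR2DS1", "functional",             "activating",           "B_associated", FALSE),
    g("KIR2DS2", "functional",             "activating",           "B_associated", FALSE),
    g("KIR2DS3", "functional",             "activating",           "B_associated", FALSE),
    g("KIR2DS4", "polymorphic_pseudogene", "activating",           "A_fixed",      TRUE),
    g("KIR2DS5", "functional",             "activating",           "B_associated", FALSE),
    g("KIR3DL1", "functional",             "inhibitory",           "A_fixed",      TRUE),
    g("KIR3DL2", "functional",             "inhibitory",           "framework",    TRUE),
    g("KIR3DL3", "functional",             "inhibitory",           "framework",    TRUE),
    g("KIR3DS1", "functional",             "activating",           "B_associated", FALSE),
    g("KIR2DP1", "pseudogene",             "framework_pseudogene", "framework",    FALSE),
    g("KIR3DP1", "pseudogene",             "framework_pseudogene", "framework",    FALSE)
  )
  if (convention == "split") {
    i <- which(fx$gene_id == "KIR2DL5")
    a <- fx[i, ]; b <- fx[i, ]
    a$gene_id <- "KIR2DL5A"; b$gene_id <- "KIR2DL5B"
    fx <- rbind(fx[seq_len(i - 1L), ], a, b, fx[seq(i + 1L, nrow(fx)), ])
  }
  rownames(fx) <- NULL
  fx
}
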