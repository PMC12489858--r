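#' Pathway registry: gene labels behind each pathway-specific PRS
#'
#' Maps each scored pathway to the set of gene labels whose lead SNPs it
#' aggregates. The partition follows the published pathway grouping of AMD
#' risk loci: complement activation, extracellular matrix (ECM) remodelling
#' (including the metalloproteinase loci ADAM19 and MMP9), lipid metabolism,
#' and the ARMS2/HTRA1 locus kept as its own score. Derived scores are
#' defined on top of the partition: the combined complement + ARMS2/HTRA1
#' score (`c_ah`) is the union of the two sets, and the global score uses
#' every surviving weight whether pathway-tagged or not.
#'
#' @return A named list of character vectors, one per pathway tag
#'   (`complement`, `ecm`, `lipid`, `arms2_htra1`).
#' @examples
#' pathway_registry()$complement
#' @export
pathway_registry <- function() {
  list(
    complement  = c("C3", "CFB/C2", "CFH", "CFI"),
    ecm         = c("ADAM19", "ADAMTS9-AS2", "COL4A3", "COL8A1", "MMP9",
                    "SYN3/TIMP3", "VEGF-A"),
    lipid       = c("ABCA1", "APOE", "CETP", "LIPC"),
    arms2_htra1 = c("ARMS2/HTRA1")
  )
}

#' @rdname pathway_registry
#' @format NULL
#' @keywords internal
pathway_tags <- function() c(names(pathway_registry()), "other")

# Resolve a gene label to its pathway tag; "" when untagged.
gene_to_pathway <- function(gene_label) {
  reg <- pathway_registry()
  out <- rep("", length(gene_label))
  for (tag in names(reg)) out[gene_label %in% reg[[tag]]] <- tag
  out
}

#' Names of the six reported scores
#'
#' The global score plus the five pathway-specific scores, in the column
#' order used throughout the package and its CSV outputs.
#' @return Character vector of score column names.
#' @export
score_names <- function() {
  c("global_prs", "ah_prs", "c_prs", "c_ah_prs", "e_prs", "l_prs")
}
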